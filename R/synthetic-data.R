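#' Specification for a synthetic irradiation time-course
#'
#' Describes a three-group (0h/2h/6h) expression experiment with planted
#' differentially expressed probes, a subset of which is organized into
#' correlated co-expression modules that each contain lncRNA probes.
#' Intra-module correlation is induced by one latent factor per module
#' with loading `sqrt(within_module_r)`, giving exchangeable pairwise
#' correlation `within_module_r` between module members.
#'
#' @param n_per_group Samples per time group.
#' @param n_probes Total probes on the array.
#' @param n_de Planted differentially expressed probes (mean shift at 2h
#'   and 6h relative to 0h).
#' @param n_modules Planted co-expression modules (taken from the DE set).
#' @param module_size Probes per module.
#' @param lnc_per_module lncRNA probes per module (>= 1).
#' @param effect_log2 Mean log2 shift of DE probes at post-irradiation times.
#' @param within_module_r Target intra-module Pearson correlation, in [0, 1).
#' @param noise_sd Residual SD on the log2 scale.
#' @param seed Integer seed; identical specs generate identical data.
#' @return A `timecourse_spec` list.
#' @export
timecourse_spec <- function(n_per_group = 50, n_probes = 2000, n_de = 200,
                            n_modules = 4, module_size = 40, lnc_per_module = 3,
                            effect_log2 = 1, within_module_r = 0.7,
                            noise_sd = 0.4, seed = 1L) {
  spec <- list(n_per_group = n_per_group, n_probes = n_probes, n_de = n_de,
               n_modules = n_modules, module_size = module_size,
               lnc_per_module = lnc_per_module, effect_log2 = effect_log2,
               within_module_r = within_module_r, noise_sd = noise_sd,
               seed = as.integer(seed))
  for (f in c("n_per_group", "n_probes", "n_modules", "module_size",
              "lnc_per_module")) check_positive_count(spec[[f]], f)
  if (spec$n_de < 0 || spec$n_de > spec$n_probes) {
    abort("n_de must satisfy 0 <= n_de <= n_probes")
  }
  if (spec$n_modules * spec$module_size > spec$n_de) {
    abort("n_modules * module_size must not exceed n_de")
  }
  if (spec$lnc_per_module > spec$module_size) {
    abort("lnc_per_module must not exceed module_size")
  }
  if (spec$within_module_r < 0 || spec$within_module_r >= 1) {
    abort("within_module_r must lie in [0, 1)")
  }
  if (spec$noise_sd <= 0) abort("noise_sd must be positive")
  structure(spec, class = "timecourse_spec")
}

#' Simulate an irradiation time-course expression experiment
#'
#' Generates a log2-scale probes-by-samples matrix with three time groups.
#' Planted DE probes shift upward by `effect_log2` at 2h and 6h; module
#' members additionally share a per-sample latent factor so their pairwise
#' correlation is approximately `within_module_r`; all remaining probes are
#' exchangeable noise around a probe-specific baseline.
#'
#' @param spec A [timecourse_spec()].
#' @return List with `expr` (expression tibble), `meta` (tibble:
#'   `sample_id`, `group`), `annotation` (tibble with biotypes; module
#'   lncRNA slots are annotated `lncRNA`), and `truth` (list: `de_probes`,
#'   `modules` tibble of probe/module, `lnc_probes`).
#' @export
simulate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "timecourse_spec"))
  withr::with_seed(spec$seed, {
    n <- 3 * spec$n_per_group
    groups <- rep(c("0h", "2h", "6h"), each = spec$n_per_group)
    sample_ids <- sprintf("S%03d", seq_len(n))
    probe_ids <- sprintf("P%05d", seq_len(spec$n_probes))

    baseline <- stats::rnorm(spec$n_probes, mean = 7, sd = 0.5)
    m <- matrix(baseline, nrow = spec$n_probes, ncol = n)

    de_idx <- seq_len(spec$n_de)
    m[de_idx, groups != "0h"] <- m[de_idx, groups != "0h"] + spec$effect_log2

    lambda <- sqrt(spec$within_module_r)
    noise <- matrix(stats::rnorm(spec$n_probes * n), spec$n_probes, n)
    module_of <- integer(spec$n_probes)
    for (k in seq_len(spec$n_modules)) {
      rows <- (k - 1) * spec$module_size + seq_len(spec$module_size)
      module_of[rows] <- k
      f <- stats::rnorm(n)
      noise[rows, ] <- lambda * matrix(f, length(rows), n, byrow = TRUE) +
        sqrt(1 - lambda^2) * noise[rows, ]
    }
    m <- m + spec$noise_sd * noise
    dimnames(m) <- list(probe_ids, sample_ids)

    biotype <- rep("gene", spec$n_probes)
    for (k in seq_len(spec$n_modules)) {
      rows <- (k - 1) * spec$module_size + seq_len(spec$lnc_per_module)
      biotype[rows] <- "lncRNA"
    }
    annotation <- tibble(
      probe_id = probe_ids,
      symbol = ifelse(biotype == "lncRNA",
                      sprintf("LNC%04d", seq_len(spec$n_probes)),
                      sprintf("G%04d", seq_len(spec$n_probes))),
      ensembl_id = sprintf("ENSG%011d", seq_len(spec$n_probes)),
      biotype = biotype
    )

    list(
      expr = matrix_to_expr(m),
      meta = tibble(sample_id = sample_ids, group = groups),
      annotation = annotation,
      truth = list(
        de_probes = probe_ids[de_idx],
        modules = tibble(probe_id = probe_ids, module = module_of),
        lnc_probes = probe_ids[biotype == "lncRNA"]
      )
    )
  })
}

#' Specification for a synthetic radiosensitivity cell panel
#'
#' Emulates a cell-line panel with a clonogenic-survival phenotype: SF2
#' (surviving fraction at 2 Gy) is drawn from two Beta distributions
#' straddling `sf2_threshold` so that exactly
#' `round(rs_fraction * n_samples)` lines are radiosensitive, and a planted
#' subset of the feature pool separates the two classes by `effect`
#' standardized units.
#'
#' @param n_samples Cell-line count.
#' @param pool_size Candidate features in the pool.
#' @param planted_size Discriminative planted subset size.
#' @param effect Standardized mean difference between RS and RR classes for
#'   planted features.
#' @param rs_fraction Proportion of lines with SF2 at or below the threshold.
#' @param sf2_threshold SF2 dichotomization threshold.
#' @param seed Integer seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_samples = 60, pool_size = 41, planted_size = 20,
                       effect = 1.5, rs_fraction = 0.5, sf2_threshold = 0.4,
                       seed = 1L) {
  spec <- list(n_samples = n_samples, pool_size = pool_size,
               planted_size = planted_size, effect = effect,
               rs_fraction = rs_fraction, sf2_threshold = sf2_threshold,
               seed = as.integer(seed))
  check_positive_count(spec$n_samples, "n_samples")
  check_positive_count(spec$pool_size, "pool_size")
  if (spec$planted_size < 0 || spec$planted_size > spec$pool_size) {
    abort("planted_size must satisfy 0 <= planted_size <= pool_size")
  }
  if (spec$effect < 0) abort("effect must be >= 0")
  if (spec$rs_fraction <= 0 || spec$rs_fraction >= 1) {
    abort("rs_fraction must lie strictly between 0 and 1")
  }
  n_rs <- round(spec$rs_fraction * spec$n_samples)
  if (n_rs == 0 || n_rs == spec$n_samples) {
    abort("rs_fraction yields an empty class at this n_samples")
  }
  structure(spec, class = "panel_spec")
}

#' Simulate a cell panel with an SF2 phenotype
#'
#' @param spec A [panel_spec()].
#' @return List with `expr` (expression tibble, `pool_size` probes x
#'   `n_samples` lines), `sf2` (tibble: `sample_id`, `sf2`), and `truth`
#'   (list: `planted` probe ids, `labels` tibble of true RS/RR state, and
#'   `class_means` tibble of per-feature RS/RR means used downstream by the
#'   patient-cohort generator).
#' @export
simulate_cell_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    n_rs <- round(spec$rs_fraction * n)
    state <- sample(rep(c("RS", "RR"), c(n_rs, n - n_rs)))
    sample_ids <- sprintf("CL%02d", seq_len(n))
    probe_ids <- sprintf("F%03d", seq_len(spec$pool_size))

    # SF2 on either side of the threshold: Beta(2,2) rescaled into each side.
    thr <- spec$sf2_threshold
    sf2 <- ifelse(state == "RS",
                  thr * stats::rbeta(n, 2, 2),
                  thr + (1 - thr) * stats::rbeta(n, 2, 2))

    baseline <- stats::rnorm(spec$pool_size, mean = 7, sd = 0.5)
    shift <- c(rep(spec$effect, spec$planted_size),
               rep(0, spec$pool_size - spec$planted_size))
    mu_rs <- baseline + shift / 2
    mu_rr <- baseline - shift / 2
    mu <- ifelse(matrix(state == "RS", spec$pool_size, n, byrow = TRUE),
                 matrix(mu_rs, spec$pool_size, n),
                 matrix(mu_rr, spec$pool_size, n))
    m <- mu + matrix(stats::rnorm(spec$pool_size * n), spec$pool_size, n)
    dimnames(m) <- list(probe_ids, sample_ids)

    list(
      expr = matrix_to_expr(m),
      sf2 = tibble(sample_id = sample_ids, sf2 = sf2),
      truth = list(
        planted = probe_ids[seq_len(spec$planted_size)],
        labels = tibble(sample_id = sample_ids, state = state),
        class_means = tibble(probe_id = probe_ids, mu_rs = mu_rs,
                             mu_rr = mu_rr, sd = 1)
      )
    )
  })
}

#' Specification for a synthetic patient survival cohort
#'
#' Patients carry a latent RS/RR state (prevalence 0.5), predictor
#' expression drawn from the matching class distribution of the cell-panel
#' model (plus a per-feature additive platform shift drawn once per
#' cohort), and exponential survival whose hazard for RR patients is
#' multiplied by `hr_rs_rtpos` in the radiotherapy-treated stratum and
#' `hr_rs_rtneg` in the untreated stratum.
#'
#' @param n_rt_pos,n_rt_neg Treated / untreated patient counts.
#' @param hr_rs_rtpos True hazard ratio, RR vs RS, among treated patients.
#' @param hr_rs_rtneg Same among untreated patients (1 = no effect).
#' @param baseline_median_months Median survival of the best (RS) group.
#' @param censor_rate Probability a patient receives random administrative
#'   censoring before the follow-up cap, in [0, 1).
#' @param followup_cap_months Maximum follow-up time.
#' @param covariates Optional tibble (`name`, `dist` in
#'   `"normal(mean,sd)"`/`"bernoulli(p)"`, `coef` log-hazard per unit).
#' @param platform_shift_sd SD of the per-feature additive platform offset
#'   (0 disables it).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_rt_pos = 300, n_rt_neg = 60, hr_rs_rtpos = 2.0,
                        hr_rs_rtneg = 1.0, baseline_median_months = 18,
                        censor_rate = 0.2, followup_cap_months = 60,
                        covariates = NULL, platform_shift_sd = 1, seed = 1L) {
  spec <- list(n_rt_pos = n_rt_pos, n_rt_neg = n_rt_neg,
               hr_rs_rtpos = hr_rs_rtpos, hr_rs_rtneg = hr_rs_rtneg,
               baseline_median_months = baseline_median_months,
               censor_rate = censor_rate,
               followup_cap_months = followup_cap_months,
               covariates = covariates, platform_shift_sd = platform_shift_sd,
               seed = as.integer(seed))
  check_positive_count(spec$n_rt_pos, "n_rt_pos")
  check_positive_count(spec$n_rt_neg, "n_rt_neg")
  if (spec$hr_rs_rtpos <= 0 || spec$hr_rs_rtneg <= 0) {
    abort("hazard ratios must be positive")
  }
  if (spec$baseline_median_months <= 0) abort("baseline_median_months must be > 0")
  if (spec$censor_rate < 0 || spec$censor_rate >= 1) {
    abort("censor_rate must lie in [0, 1)")
  }
  if (spec$followup_cap_months <= 0) abort("followup_cap_months must be > 0")
  if (spec$platform_shift_sd < 0) abort("platform_shift_sd must be >= 0")
  structure(spec, class = "cohort_spec")
}

parse_cov_dist <- function(dist, n) {
  m <- regmatches(dist, regexec("^(normal|bernoulli)\\(([^)]*)\\)$", dist))[[1]]
  if (length(m) == 0) abort(paste0("unparseable covariate distribution: ", dist))
  args <- as.numeric(strsplit(m[3], ",")[[1]])
  switch(m[2],
    normal = stats::rnorm(n, args[1], args[2]),
    bernoulli = stats::rbinom(n, 1, args[1])
  )
}

#' Simulate a patient cohort for survival validation
#'
#' @param spec A [cohort_spec()].
#' @param predictors Either the `class_means` tibble from
#'   [simulate_cell_panel()] truth (columns `probe_id`, `mu_rs`, `mu_rr`,
#'   `sd`), or a character vector of probe ids to subset from it.
#' @param class_means Required when `predictors` is a character vector.
#' @return List with `cohort` (tibble: `patient_id`, one column per
#'   predictor probe, `os_months`, `event`, `rt`, covariate columns) and
#'   `truth` (tibble: `patient_id`, true `state`).
#' @export
simulate_patient_cohort <- function(spec, predictors, class_means = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.character(predictors)) {
    if (is.null(class_means)) abort("class_means needed when predictors is a character vector")
    predictors <- dplyr::filter(class_means, .data$probe_id %in% predictors)
  }
  if (!is.data.frame(predictors) || nrow(predictors) == 0) {
    abort("empty predictor set")
  }
  stopifnot(all(c("probe_id", "mu_rs", "mu_rr", "sd") %in% names(predictors)))

  withr::with_seed(spec$seed, {
    n <- spec$n_rt_pos + spec$n_rt_neg
    rt <- rep(c("RT+", "RT-"), c(spec$n_rt_pos, spec$n_rt_neg))
    state <- sample(c("RS", "RR"), n, replace = TRUE)
    patient_id <- sprintf("PT%04d", seq_len(n))

    p <- nrow(predictors)
    shift <- stats::rnorm(p, 0, spec$platform_shift_sd)
    mu <- ifelse(matrix(state == "RS", p, n, byrow = TRUE),
                 matrix(predictors$mu_rs, p, n),
                 matrix(predictors$mu_rr, p, n))
    x <- mu + shift + matrix(stats::rnorm(p * n, 0, predictors$sd), p, n)
    rownames(x) <- predictors$probe_id

    cov_tab <- NULL
    log_hr_cov <- rep(0, n)
    if (!is.null(spec$covariates) && nrow(spec$covariates) > 0) {
      cov_tab <- as_tibble(stats::setNames(
        lapply(spec$covariates$dist, parse_cov_dist, n = n),
        spec$covariates$name
      ))
      log_hr_cov <- as.matrix(cov_tab) %*% spec$covariates$coef
    }

    base_rate <- log(2) / spec$baseline_median_months
    hr <- ifelse(state == "RR",
                 ifelse(rt == "RT+", spec$hr_rs_rtpos, spec$hr_rs_rtneg), 1)
    t_event <- stats::rexp(n, rate = base_rate * hr * exp(log_hr_cov))
    t_cens <- ifelse(stats::runif(n) < spec$censor_rate,
                     stats::runif(n, 0, spec$followup_cap_months),
                     spec$followup_cap_months)
    os <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    cohort <- dplyr::bind_cols(
      tibble(patient_id = patient_id),
      as_tibble(t(x), .name_repair = "minimal") |>
        stats::setNames(predictors$probe_id),
      tibble(os_months = os, event = event, rt = rt)
    )
    if (!is.null(cov_tab)) cohort <- dplyr::bind_cols(cohort, cov_tab)

    list(cohort = cohort,
         truth = tibble(patient_id = patient_id, state = state))
  })
}

#' Write synthetic data to the on-disk formats the readers consume
#'
#' Emits the tab-delimited expression matrix, CSV metadata, CSV annotation
#' (when present) and a `truth.json` sidecar recording planted parameters.
#'
#' @param sim Output of one of the `simulate_*` generators.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$expr)) write_expression(sim$expr, file.path(dir, "expression.tsv"))
  if (!is.null(sim$meta)) readr::write_csv(sim$meta, file.path(dir, "metadata.csv"))
  if (!is.null(sim$annotation)) readr::write_csv(sim$annotation, file.path(dir, "annotation.csv"))
  if (!is.null(sim$sf2)) readr::write_csv(sim$sf2, file.path(dir, "sf2.csv"))
  if (!is.null(sim$cohort)) readr::write_csv(sim$cohort, file.path(dir, "clinical.csv"))
  if (!is.null(sim$truth)) {
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}
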