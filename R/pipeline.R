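#' Pipeline configuration
#'
#' Bundles every stage's parameters plus one global seed. Per-stage seeds
#' are derived deterministically from the global seed and the stage name,
#' so any stage can be rerun in isolation and identical configs give
#' byte-identical summaries.
#'
#' @param timecourse A [timecourse_spec()] for the irradiation screen.
#' @param panel A [panel_spec()] for the cell panel; its `pool_size` is
#'   overridden by the candidate pool emerging from the network stage.
#' @param cohort A [cohort_spec()] for the validation cohort.
#' @param alpha,fc_min Differential-expression thresholds.
#' @param network A [network_config()].
#' @param r_min Pair-correlation threshold.
#' @param ga A [ga_config()].
#' @param n_perm Permutation-null draws.
#' @param survival_cap Follow-up truncation (months).
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(timecourse = timecourse_spec(),
                            panel = panel_spec(),
                            cohort = cohort_spec(),
                            alpha = 1e-4, fc_min = 1.3,
                            network = network_config(),
                            r_min = 0.75,
                            ga = ga_config(),
                            n_perm = 1000,
                            survival_cap = 24,
                            seed = 1L) {
  structure(list(timecourse = timecourse, panel = panel, cohort = cohort,
                 alpha = alpha, fc_min = fc_min, network = network,
                 r_min = r_min, ga = ga, n_perm = n_perm,
                 survival_cap = survival_cap, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `timecourse`,
#' `panel`, `cohort`, `network` and `ga` blocks hold the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, block %||% list())
  pipeline_config(
    timecourse = build(timecourse_spec, y$timecourse),
    panel = build(panel_spec, y$panel),
    cohort = build(cohort_spec, y$cohort),
    alpha = y$alpha %||% 1e-4,
    fc_min = y$fc_min %||% 1.3,
    network = build(network_config, y$network),
    r_min = y$r_min %||% 0.75,
    ga = build(ga_config, y$ga),
    n_perm = y$n_perm %||% 1000,
    survival_cap = y$survival_cap %||% 24,
    seed = y$seed %||% 1L
  )
}

pipe_log <- function(log_path, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the full radiosensitivity-modelling pipeline
#'
#' Executes the workflow end to end on synthetic inputs: time-course
#' simulation, differential-expression screen, per-time-point
#' co-expression networks and gene-lncRNA pairs, candidate pooling, GA
#' predictor search on a simulated cell panel (whose feature ids are the
#' candidate pool), permutation null, and survival validation in a
#' simulated patient cohort. Each stage's output is written to `out_dir`
#' before the next starts, and a `summary.json` records the headline
#' numbers. Identical config (including seed) gives an identical summary.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return The summary list, invisibly; side effects under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    pipe_log(log_path, "stage ", name, " started")
    out <- tryCatch(fun(), error = function(e) {
      pipe_log(log_path, "stage ", name, " FAILED: ", conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    pipe_log(log_path, "stage ", name, " done in ",
             sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  # 1. synthetic time-course
  tc <- run_stage("timecourse", function() {
    spec <- config$timecourse
    spec$seed <- derive_seed(config$seed, "timecourse")
    sim <- simulate_timecourse(spec)
    write_synthetic(sim, file.path(out_dir, "01_timecourse"))
    sim
  })

  # 2. differential expression
  de <- run_stage("diffexpr", function() {
    res <- run_diffexpr(tc$expr, tc$meta)
    sel <- select_differential(res, tc$annotation,
                               alpha = config$alpha, fc_min = config$fc_min)
    readr::write_tsv(res, file.path(out_dir, "02_diffexpr.tsv"))
    readr::write_tsv(sel$summary, file.path(out_dir, "02_de_sets.tsv"))
    list(results = res, selection = sel)
  })

  # 3. co-expression networks per post-irradiation time point
  pairs <- run_stage("coexpression", function() {
    union_expr <- dplyr::filter(tc$expr, .data$probe_id %in% de$selection$union)
    per_time <- purrr::map_dfr(c("2h", "6h"), function(tp) {
      sams <- tc$meta$sample_id[tc$meta$group == tp]
      ex <- union_expr[, c("probe_id", sams)]
      if (nrow(ex) < 3) return(NULL)
      beta <- pick_soft_threshold(ex, config$network)$power
      tom <- tom_similarity(adjacency(ex, beta))
      part <- cluster_modules(tom, config$network)
      extract_pairs(ex, part, tc$annotation, r_min = config$r_min,
                    time_label = tp)
    })
    readr::write_tsv(per_time, file.path(out_dir, "03_pairs.tsv"))
    per_time
  })
  if (nrow(pairs) == 0) abort("pipeline stage 'coexpression' produced no pairs")
  pool <- pool_predictor_candidates(pairs)

  # 4. cell panel + GA predictor search
  ga <- run_stage("ga", function() {
    pspec <- config$panel
    pspec$pool_size <- length(pool$pool)
    if (pspec$planted_size > pspec$pool_size) {
      pspec$planted_size <- max(1L, pspec$pool_size %/% 2)
    }
    pspec$seed <- derive_seed(config$seed, "panel")
    sim <- simulate_cell_panel(pspec)
    # the panel measures the pooled candidates: carry their probe ids over
    id_map <- stats::setNames(pool$pool, sim$expr$probe_id)
    sim$expr$probe_id <- unname(id_map[sim$expr$probe_id])
    sim$truth$planted <- unname(id_map[sim$truth$planted])
    sim$truth$class_means$probe_id <- unname(id_map[sim$truth$class_means$probe_id])
    write_synthetic(sim, file.path(out_dir, "04_panel"))
    labels <- dichotomize_sf2(sim$sf2)
    gcfg <- config$ga
    if (gcfg$k > length(pool$pool)) {
      abort(sprintf("GA k (%d) exceeds candidate pool size (%d)",
                    gcfg$k, length(pool$pool)))
    }
    gcfg$seed <- derive_seed(config$seed, "ga")
    fit <- evolve(sim$expr, labels, pool$pool, gcfg)
    readr::write_tsv(fit$trace[c("generation", "best_accuracy", "mean_accuracy")],
                     file.path(out_dir, "04_ga_trace.tsv"))
    readr::write_lines(fit$best_set, file.path(out_dir, "04_best_set.txt"))
    list(panel = sim, labels = labels, fit = fit, ga_config = gcfg)
  })

  # 5. permutation null
  perm <- run_stage("permutation", function() {
    y <- align_labels(ga$panel$expr, ga$labels)
    fold_list <- make_cv_folds(y, ga$ga_config$cv_folds,
                               fold_seed = derive_seed(ga$ga_config$seed, "cv_folds"))
    pt <- permutation_null(ga$panel$expr, ga$labels, pool$pool,
                           observed = ga$fit$best_accuracy,
                           k = ga$ga_config$k, n_perm = config$n_perm,
                           folds = fold_list,
                           seed = derive_seed(config$seed, "permutation"))
    readr::write_tsv(tidy(pt), file.path(out_dir, "05_null_accuracies.tsv"))
    pt
  })

  # 6. survival validation
  val <- run_stage("survival", function() {
    model <- train_final_model(ga$panel$expr, ga$labels, ga$fit$best_set)
    write_model(model, file.path(out_dir, "06_model.json"))
    cspec <- config$cohort
    cspec$seed <- derive_seed(config$seed, "cohort")
    cm <- dplyr::filter(ga$panel$truth$class_means,
                        .data$probe_id %in% ga$fit$best_set)
    sim <- simulate_patient_cohort(cspec, cm)
    readr::write_csv(sim$cohort, file.path(out_dir, "06_cohort.csv"))
    report <- validate_cohort(model, sim$cohort, cap = config$survival_cap)
    readr::write_tsv(tidy(report), file.path(out_dir, "06_cox.tsv"))
    report
  })

  summary <- list(
    seed = config$seed,
    n_de_2h = length(de$selection$set_2h),
    n_de_6h = length(de$selection$set_6h),
    n_de_union = length(de$selection$union),
    n_pairs = nrow(pairs),
    pool_genes = length(pool$gene),
    pool_lncRNAs = length(pool$lncRNA),
    ga_best_accuracy = ga$fit$best_accuracy,
    empirical_p = perm$empirical_p,
    logrank_p = lapply(val$strata, function(s) s$logrank$p_value)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(log_path, "pipeline complete")
  invisible(summary)
}
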