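#' Train and freeze the final radiosensitivity classifier
#'
#' Standardizes each predictor across the training panel, fits a
#' linear-kernel SVM (cost 1), and freezes the result as explicit weights,
#' intercept and standardization constants, so prediction is a plain
#' `w . z + b` that can be serialized and reapplied anywhere.
#'
#' @param expr Panel expression tibble (`probe_id` + sample columns).
#' @param labels Output of [dichotomize_sf2()].
#' @param predictors Character vector of predictor probe ids.
#' @return Object of class `rs_model`: `predictors`, `weights`,
#'   `intercept`, `center`, `scale`, `positive_class`, `negative_class`.
#' @export
train_final_model <- function(expr, labels, predictors) {
  validate_expr(expr, min_samples = 2)
  y <- align_labels(expr, labels)
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present")
  missing <- setdiff(predictors, expr$probe_id)
  if (length(missing)) {
    abort(paste0("predictor probes absent from panel: ",
                 paste(missing, collapse = ", ")))
  }
  x <- t(expr_to_matrix(expr))[, predictors, drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(x = z, y = droplevels(y), kernel = "linear", cost = 1,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  names(w) <- predictors
  # e1071's decision value is w.x - rho, positive for the first class of
  # the "A/B" pair named in the decision-value column.
  dv <- stats::predict(fit, z[1:2, , drop = FALSE], decision.values = TRUE)
  pair <- colnames(attr(dv, "decision.values"))[1]
  pos <- strsplit(pair, "/", fixed = TRUE)[[1]][1]
  lev <- levels(droplevels(y))
  structure(list(predictors = predictors, weights = w, intercept = -fit$rho,
                 center = mu, scale = sdv,
                 positive_class = pos,
                 negative_class = setdiff(lev, pos)),
            class = "rs_model")
}

#' @export
print.rs_model <- function(x, ...) {
  cat(sprintf("Frozen linear radiosensitivity classifier: %d predictors\n",
              length(x$predictors)))
  invisible(x)
}

rs_decision <- function(model, z) {
  unname(drop(z[, model$predictors, drop = FALSE] %*% model$weights +
                model$intercept))
}

#' Predict RS/RR labels with a frozen classifier
#'
#' @param object An `rs_model`.
#' @param newdata Samples-by-features matrix or tibble containing every
#'   predictor column, already on the model's standardized scale.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.rs_model <- function(object, newdata, ...) {
  z <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  d <- rs_decision(object, z)
  factor(ifelse(d > 0, object$positive_class, object$negative_class),
         levels = c("RR", "RS"))
}

#' Serialize / restore a frozen classifier
#'
#' Plain-text JSON at full double precision, so a save/load round trip
#' reproduces predictions exactly.
#'
#' @param model An `rs_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `rs_model` (read).
#' @export
write_model <- function(model, path) {
  out <- unclass(model)
  # doubles as 17-significant-digit strings: bit-exact on the way back
  for (f in c("weights", "intercept", "center", "scale")) {
    out[[f]] <- sprintf("%.17g", out[[f]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$intercept <- as.numeric(raw$intercept)
  raw$weights <- stats::setNames(as.numeric(raw$weights), raw$predictors)
  raw$center <- stats::setNames(as.numeric(raw$center), raw$predictors)
  raw$scale <- stats::setNames(as.numeric(raw$scale), raw$predictors)
  structure(raw, class = "rs_model")
}

#' Classify patients with the frozen panel model
#'
#' Predictor features are standardized within the cohort (each predictor
#' centered and scaled across patients) before applying the frozen
#' weights. This per-cohort standardization absorbs additive platform
#' differences between the training panel and the patient arrays, and
#' makes the output independent of patient order.
#'
#' @param model An `rs_model`.
#' @param cohort Patient tibble with `patient_id` and one column per
#'   predictor probe.
#' @param standardize `"cohort"` (default) re-standardizes within the
#'   cohort; `"training"` applies the panel's frozen center/scale.
#' @return Tibble: `patient_id`, `decision`, `pred_class`.
#' @export
classify_patients <- function(model, cohort, standardize = c("cohort", "training")) {
  standardize <- match.arg(standardize)
  missing <- setdiff(model$predictors, names(cohort))
  if (length(missing)) {
    abort(paste0("cohort missing predictor columns: ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.matrix(cohort[, model$predictors, drop = FALSE])
  if (standardize == "cohort") {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
  } else {
    mu <- model$center
    sdv <- model$scale
  }
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  d <- rs_decision(model, z)
  tibble(patient_id = cohort$patient_id,
         decision = d,
         pred_class = factor(ifelse(d > 0, model$positive_class,
                                    model$negative_class),
                             levels = c("RR", "RS")))
}

#' Truncate follow-up at a time cap
#'
#' Administrative truncation: observations beyond the cap become censored
#' at the cap; earlier observations are unchanged.
#'
#' @param cohort Patient tibble with `os_months` and `event` columns.
#' @param cap Truncation time (default 24 months, i.e. 2-year survival).
#' @return The cohort with truncated `os_months`/`event`.
#' @export
truncate_followup <- function(cohort, cap = 24) {
  if (cap <= 0) abort("cap must be positive")
  dplyr::mutate(cohort,
                event = ifelse(.data$os_months > cap, 0L, as.integer(.data$event)),
                os_months = pmin(.data$os_months, cap))
}

#' Kaplan-Meier curves and the two-sample log-rank test
#'
#' Product-limit survival estimates per group plus the standard log-rank
#' statistic (sum of observed-minus-expected deaths over pooled risk sets,
#' squared and scaled by its hypergeometric variance) referred to
#' chi-squared with 1 degree of freedom.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 death, 0 censored).
#' @param groups Two-level group assignment.
#' @return Object of class `surv_comparison`: `curves` tibble (`group`,
#'   `time`, `survival`, `n_risk`, `n_event`), `statistic`, `p_value`,
#'   `group_sizes`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("need exactly 2 nonempty groups")
  if (any(table(groups) == 0)) abort("a group has no observations")
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- sd_fit$chisq
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  curves <- tibble(
    group = rep(sub("^groups=", "", names(sf$strata)), sf$strata),
    time = sf$time, survival = sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event
  )
  structure(list(curves = curves, statistic = stat, p_value = p,
                 group_sizes = table(groups)),
            class = "surv_comparison")
}

#' @export
print.surv_comparison <- function(x, ...) {
  cat(sprintf("Log-rank: chi-squared = %.3f, p = %.4g (groups: %s)\n",
              x$statistic, x$p_value,
              paste(sprintf("%s n=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `surv_comparison` object.
#' @param ... Unused.
#' @method tidy surv_comparison
#' @export
tidy.surv_comparison <- function(x, ...) x$curves

#' @rdname km_logrank
#' @method glance surv_comparison
#' @export
glance.surv_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_group1 = as.integer(x$group_sizes[1]),
         n_group2 = as.integer(x$group_sizes[2]))
}

#' @rdname km_logrank
#' @param object A `surv_comparison` object.
#' @method autoplot surv_comparison
#' @export
autoplot.surv_comparison <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; one row per term with
#' the hazard ratio, the SE of the log hazard and the Wald p-value.
#' Patients with missing values in any term are dropped from this fit
#' only, with a message giving the count.
#'
#' @param data Patient tibble.
#' @param terms Character vector of covariate column names (the first is
#'   conventionally the model's RS/RR group).
#' @param time_col,event_col Names of the time and event columns.
#' @return Tibble: `term`, `hazard_ratio`, `se_log_hr`, `p_value`, plus
#'   attributes `n` and `n_events`.
#' @export
cox_fit <- function(data, terms, time_col = "os_months", event_col = "event") {
  miss <- setdiff(c(terms, time_col, event_col), names(data))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  use <- stats::complete.cases(data[, c(terms, time_col, event_col)])
  if (sum(!use)) message(sum(!use), " patients dropped from Cox fit (missing values)")
  d <- data[use, ]
  if (sum(d[[event_col]]) < 1) abort("no events in the data")
  const <- terms[vapply(terms, function(t) length(unique(d[[t]])) < 2, TRUE)]
  if (length(const)) {
    abort(paste0("constant covariates: ", paste(const, collapse = ", ")))
  }
  f <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", terms), collapse = " + ")
  ))
  fit <- survival::coxph(f, data = d, ties = "efron")
  s <- summary(fit)
  out <- tibble(
    term = rownames(s$coefficients),
    hazard_ratio = s$coefficients[, "exp(coef)"],
    se_log_hr = s$coefficients[, "se(coef)"],
    p_value = s$coefficients[, "Pr(>|z|)"]
  )
  attr(out, "n") <- s$n
  attr(out, "n_events") <- s$nevent
  out
}

#' Validate the frozen classifier in a patient cohort
#'
#' Runs the full validation chain: truncate follow-up, classify patients
#' (per-cohort standardization), then within each radiotherapy stratum
#' compare predicted-RS vs predicted-RR survival by Kaplan-Meier/log-rank
#' and a Cox fit of the model group plus any covariates. The expected
#' pattern is a survival split only in the treated (RT+) stratum. In the
#' Cox fit the model group is coded RR = 1 vs RS = 0, so a hazard ratio
#' above 1 means predicted-radioresistant patients die faster.
#'
#' @param model An `rs_model`.
#' @param cohort Patient tibble (`patient_id`, predictor columns,
#'   `os_months`, `event`, `rt`, covariates).
#' @param cap Follow-up truncation in months (default 24).
#' @param covariates Extra covariate column names for the Cox fit.
#' @return Object of class `cohort_validation`: per-stratum list with
#'   `n_rs`, `n_rr`, `logrank` (`surv_comparison`) and `cox` (tibble),
#'   plus `predictions`.
#' @export
validate_cohort <- function(model, cohort, cap = 24, covariates = character()) {
  if (!all(c("os_months", "event", "rt") %in% names(cohort))) {
    abort("cohort needs os_months, event and rt columns")
  }
  strata <- unique(cohort$rt)
  if (length(strata) < 2) abort("cohort must contain both RT strata")
  trunc <- truncate_followup(cohort, cap)
  pred <- classify_patients(model, trunc)
  d <- dplyr::left_join(trunc, pred, by = "patient_id") |>
    dplyr::mutate(model_group = as.integer(.data$pred_class == "RR"))

  stratum_order <- c(intersect(c("RT+", "RT-"), strata),
                     setdiff(sort(strata), c("RT+", "RT-")))
  per_stratum <- lapply(stats::setNames(nm = stratum_order),
                        function(s) {
    ds <- dplyr::filter(d, .data$rt == s)
    lr <- km_logrank(ds$os_months, ds$event, ds$pred_class)
    cx <- cox_fit(ds, c("model_group", covariates))
    list(n_rs = sum(ds$pred_class == "RS"),
         n_rr = sum(ds$pred_class == "RR"),
         logrank = lr, cox = cx)
  })
  structure(list(strata = per_stratum, predictions = pred, cap = cap),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    cat(sprintf("%s: RS n=%d, RR n=%d, log-rank p = %.4g\n",
                s, st$n_rs, st$n_rr, st$logrank$p_value))
  }
  invisible(x)
}

#' @rdname validate_cohort
#' @param x A `cohort_validation` object.
#' @param ... Unused.
#' @method tidy cohort_validation
#' @export
tidy.cohort_validation <- function(x, ...) {
  purrr::map_dfr(names(x$strata), function(s) {
    dplyr::mutate(x$strata[[s]]$cox, stratum = s, .before = 1)
  })
}

#' @rdname validate_cohort
#' @method glance cohort_validation
#' @export
glance.cohort_validation <- function(x, ...) {
  purrr::map_dfr(names(x$strata), function(s) {
    st <- x$strata[[s]]
    tibble(stratum = s, n_rs = st$n_rs, n_rr = st$n_rr,
           logrank_p = st$logrank$p_value,
           model_hr = st$cox$hazard_ratio[st$cox$term == "model_group"],
           model_p = st$cox$p_value[st$cox$term == "model_group"])
  })
}
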