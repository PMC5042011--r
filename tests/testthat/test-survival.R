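make_panel_model <- function(effect = 2, seed = 2, k = 20) {
  sim <- simulate_cell_panel(panel_spec(effect = effect, seed = seed))
  lab <- dichotomize_sf2(sim$sf2)
  model <- train_final_model(sim$expr, lab, sim$truth$planted[seq_len(k)])
  list(sim = sim, lab = lab, model = model)
}

test_that("the frozen classifier reproduces its own training decisions", {
  setup <- make_panel_model(effect = 5)
  model <- setup$model
  # separable training data: perfect resubstitution accuracy
  x <- t(expr_to_matrix(setup$sim$expr))[, model$predictors]
  z <- scale(x, model$center, model$scale)
  pred <- predict(model, z)
  truth <- setup$sim$truth$labels$state
  expect_equal(as.character(pred), truth)

  # decision values equal w . z + b recomputed by hand on a 3-feature toy
  toy <- make_panel_model(effect = 3, seed = 7, k = 3)
  zt <- scale(t(expr_to_matrix(toy$sim$expr))[, toy$model$predictors],
              toy$model$center, toy$model$scale)
  by_hand <- as.vector(zt %*% toy$model$weights) + toy$model$intercept
  expect_equal(rs_decision(toy$model, zt), by_hand)
  # and the sign rule maps onto e1071's own predictions
  efit <- e1071::svm(x = zt, y = factor(toy$sim$truth$labels$state,
                                        levels = c("RR", "RS")),
                     kernel = "linear", cost = 1, scale = FALSE)
  expect_equal(as.character(predict(toy$model, zt)),
               as.character(predict(efit, zt)))

  # single-class training is refused
  one_class <- dplyr::mutate(setup$lab, label = factor("RS", levels = c("RR", "RS")))
  expect_error(train_final_model(setup$sim$expr, one_class,
                                 model$predictors), "both classes")
})

test_that("model serialization round-trips predictions exactly", {
  setup <- make_panel_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(setup$model, f)
  back <- read_model(f)
  cohort <- simulate_patient_cohort(cohort_spec(seed = 3),
                                    setup$sim$truth$class_means[1:20, ])$cohort
  expect_identical(classify_patients(setup$model, cohort),
                   classify_patients(back, cohort))
})

test_that("patient classification standardizes per cohort and recovers truth", {
  setup <- make_panel_model(effect = 2, seed = 2)
  sim <- simulate_patient_cohort(
    cohort_spec(n_rt_pos = 300, n_rt_neg = 60, platform_shift_sd = 1, seed = 4),
    setup$sim$truth$class_means[1:20, ])
  pred <- classify_patients(setup$model, sim$cohort)
  acc <- mean(as.character(pred$pred_class) == sim$truth$state)
  expect_gte(acc, 0.9)

  # a patient sitting at the standardized RS training centroid is called RS
  rs_idx <- setup$sim$truth$labels$state == "RS"
  x <- t(expr_to_matrix(setup$sim$expr))[, setup$model$predictors]
  z <- scale(x, setup$model$center, setup$model$scale)
  centroid <- colMeans(z[rs_idx, , drop = FALSE])
  expect_equal(as.character(predict(setup$model, t(centroid))), "RS")

  # duplicating every patient leaves labels unchanged
  dup <- dplyr::bind_rows(sim$cohort,
                          dplyr::mutate(sim$cohort,
                                        patient_id = paste0(patient_id, "b")))
  pred_dup <- classify_patients(setup$model, dup)
  expect_equal(pred_dup$pred_class[seq_len(nrow(sim$cohort))], pred$pred_class)

  expect_error(classify_patients(setup$model, sim$cohort[, -2]),
               setup$model$predictors[1])
})

test_that("follow-up truncation censors beyond the cap", {
  cohort <- tibble::tibble(patient_id = sprintf("p%d", 1:10),
                           os_months = c(30, 10, 24, 25, 2, 40, 23.9, 24.1, 5, 60),
                           event = c(1, 1, 1, 0, 0, 1, 1, 1, 1, 0))
  out <- truncate_followup(cohort, cap = 24)
  expect_equal(out$os_months, pmin(cohort$os_months, 24))
  expect_equal(out$event[1], 0L)
  expect_equal(out$event[2], 1L)
  # events after truncation = events observed at or before the cap
  expect_equal(sum(out$event),
               sum(cohort$event == 1 & cohort$os_months <= 24))
  expect_error(truncate_followup(cohort, cap = -1), "cap")
})

test_that("log-rank matches the risk-set enumeration oracle", {
  # identical groups: statistic 0, p = 1
  t0 <- rep(c(1, 2, 3, 4), 2)
  e0 <- rep(c(1, 1, 0, 1), 2)
  g0 <- rep(c("A", "B"), each = 4)
  same <- km_logrank(t0, e0, g0)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  # separated groups: match the hand-tabulated statistic
  times <- c(1, 2, 3, 4, 5, 6)
  events <- rep(1, 6)
  groups <- rep(c("A", "B"), each = 3)
  lr <- km_logrank(times, events, groups)
  expect_equal(lr$statistic, logrank_brute_force(times, events, groups),
               tolerance = 1e-12)

  # KM with no censoring equals the empirical survival function
  km_a <- lr$curves[lr$curves$group == "A", ]
  expect_equal(km_a$survival, c(2, 1, 0) / 3)
  # curves start at 1 and never increase; at-risk counts never increase
  for (grp in c("A", "B")) {
    cv <- lr$curves[lr$curves$group == grp, ]
    expect_true(all(diff(cv$survival) <= 0))
    expect_true(all(diff(cv$n_risk) <= 0))
    expect_lte(max(cv$survival), 1)
  }

  # invariance under relabeling that preserves time order
  lr2 <- km_logrank(times * 10, events, groups)
  expect_equal(lr2$statistic, lr$statistic)

  expect_error(km_logrank(times, events, rep("A", 6)), "2 nonempty groups")
})

test_that("Cox fit matches a brute-force partial-likelihood oracle", {
  times <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9, 7.4, 9.8)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  d <- tibble::tibble(os_months = times, event = events, grp = x)
  fit <- cox_fit(d, "grp")
  beta_hat <- stats::optimize(function(b) -cox_loglik_1cov(b, times, events, x),
                              c(-5, 5), tol = 1e-10)$minimum
  expect_equal(log(fit$hazard_ratio), beta_hat, tolerance = 1e-6)

  expect_error(cox_fit(dplyr::mutate(d, event = 0), "grp"), "no events")
  expect_error(cox_fit(dplyr::mutate(d, grp = 1), "grp"), "constant")
})

test_that("Cox estimation is calibrated against the survival generator", {
  panel <- simulate_cell_panel(panel_spec(effect = 2, seed = 2))
  cm <- panel$truth$class_means[1:20, ]
  hrs <- numeric(100)
  null_cover <- logical(50)
  for (r in 1:100) {
    sim <- simulate_patient_cohort(
      cohort_spec(n_rt_pos = 450, n_rt_neg = 50, hr_rs_rtpos = 2,
                  censor_rate = 0.2, seed = 7000 + r), cm)
    d <- dplyr::left_join(sim$cohort, sim$truth, by = "patient_id") |>
      dplyr::filter(rt == "RT+") |>
      dplyr::mutate(rr = as.integer(state == "RR"))
    hrs[r] <- cox_fit(d, "rr")$hazard_ratio
    if (r <= 50) {
      # independent covariate: HR must hover around 1
      d$noise_cov <- withr::with_seed(8000 + r, rnorm(nrow(d)))
      hr0 <- cox_fit(d, "noise_cov")$hazard_ratio
      null_cover[r] <- hr0 > 0.8 && hr0 < 1.25
    }
  }
  expect_gt(mean(hrs), 1.8)
  expect_lt(mean(hrs), 2.2)
  expect_gte(mean(null_cover), 0.95)
})

test_that("cohort validation separates the treated stratum only", {
  setup <- make_panel_model(effect = 2, seed = 2)
  cm <- setup$sim$truth$class_means[1:20, ]
  sim <- simulate_patient_cohort(
    cohort_spec(n_rt_pos = 400, n_rt_neg = 100, hr_rs_rtpos = 2.5,
                hr_rs_rtneg = 1.0, seed = 77), cm)
  report <- validate_cohort(setup$model, sim$cohort, cap = 24)
  g <- glance(report)
  expect_setequal(g$stratum, c("RT+", "RT-"))
  expect_lt(g$logrank_p[g$stratum == "RT+"], 0.05)
  expect_gt(g$model_hr[g$stratum == "RT+"], 1)

  # deterministic given cohort + model
  report2 <- validate_cohort(setup$model, sim$cohort, cap = 24)
  expect_identical(glance(report2), g)

  td <- tidy(report)
  expect_true(all(c("stratum", "term", "hazard_ratio", "p_value") %in% names(td)))
  expect_s3_class(ggplot2::autoplot(report$strata[["RT+"]]$logrank), "ggplot")

  expect_error(validate_cohort(setup$model,
                               dplyr::filter(sim$cohort, rt == "RT+")),
               "both RT strata")
})
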