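test_that("SF2 dichotomization applies the threshold and tie rule", {
  lab <- dichotomize_sf2(c(a = 0.2, b = 0.9, c = 0.4), threshold = 0.4)
  expect_equal(as.character(lab$label), c("RS", "RR", "RS"))
  expect_error(dichotomize_sf2(c(0.5, 1.2)), "\\(0, 1\\]")

  # one-class labels are produced, but downstream fitting refuses them
  sim <- simulate_cell_panel(panel_spec(seed = 1))
  lab1 <- dichotomize_sf2(sim$sf2, threshold = 0.999)
  expect_true(all(lab1$label == "RS"))
  expect_error(cv_accuracy(sim$expr, lab1, sim$expr$probe_id[1:5]),
               "both classes")
})

test_that("cross-validated accuracy matches an explicit fold-loop oracle", {
  set.seed(44)
  n <- 12
  y <- factor(rep(c("RR", "RS"), each = 6), levels = c("RR", "RS"))
  m <- matrix(rnorm(3 * n), 3, n)
  m[, y == "RS"] <- m[, y == "RS"] + 1.2
  expr <- toy_expr(m)
  labels <- tibble::tibble(sample_id = names(expr)[-1], label = y)
  folds <- make_cv_folds(y, folds = 3, fold_seed = 9)

  acc <- cv_accuracy(expr, labels, expr$probe_id, folds = folds)

  # independent oracle: loop folds, standardize by training stats, call the
  # SVM directly, pool correct predictions
  x <- t(expr_to_matrix(expr))
  correct <- 0
  for (te in folds) {
    tr_x <- x[-te, , drop = FALSE]
    mu <- colMeans(tr_x)
    sds <- apply(tr_x, 2, sd)
    fit <- e1071::svm(x = scale(tr_x, mu, sds), y = y[-te],
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, scale(x[te, , drop = FALSE], mu, sds))
    correct <- correct + sum(pred == y[te])
  }
  expect_equal(acc, correct / n)
})

test_that("cv accuracy hits the expected extremes", {
  sim <- simulate_cell_panel(panel_spec(effect = 5, seed = 3))
  lab <- dichotomize_sf2(sim$sf2)
  expect_equal(cv_accuracy(sim$expr, lab, sim$truth$planted, folds = 5,
                           fold_seed = 1), 1.0)

  # labels shuffled independently of the data: chance level
  withr::with_seed(10, {
    shuffled <- lab
    shuffled$label <- sample(lab$label)
  })
  acc0 <- cv_accuracy(sim$expr, shuffled, sim$truth$planted, folds = 5,
                      fold_seed = 1)
  expect_lt(abs(acc0 - 0.5), 0.15)

  # deterministic given the fold partition
  expect_identical(
    cv_accuracy(sim$expr, lab, sim$truth$planted, folds = 5, fold_seed = 7),
    cv_accuracy(sim$expr, lab, sim$truth$planted, folds = 5, fold_seed = 7))

  expect_error(make_cv_folds(factor(rep(c("RR", "RS"), 3)), folds = 7), "folds")
  expect_warning(make_cv_folds(factor(rep(c("RR", "RS"), c(3, 9))), folds = 5),
                 "reducing folds")
})

test_that("population initialization respects size, membership and seed", {
  pool <- sprintf("F%03d", 1:41)
  cfg <- ga_config(population = 100, k = 20, seed = 2)
  withr::with_seed(2, pop <- init_population(pool, cfg))
  expect_length(pop, 100)
  expect_true(all(vapply(pop, length, 0L) == 20))
  expect_true(all(vapply(pop, anyDuplicated, 0L) == 0))
  expect_true(all(unlist(pop) %in% pool))
  withr::with_seed(2, pop2 <- init_population(pool, cfg))
  expect_identical(pop, pop2)

  # pool size = k: every chromosome is the whole pool
  cfg2 <- ga_config(population = 5, k = 4)
  pop3 <- init_population(letters[1:4], cfg2)
  expect_true(all(vapply(pop3, function(s) setequal(s, letters[1:4]), TRUE)))
  expect_error(init_population(letters[1:3], cfg2), "pool smaller")
})

test_that("roulette selection is fitness-proportional", {
  withr::with_seed(5, {
    expect_true(all(replicate(50, select_parents(c(1, 0))) == 1))

    draws <- replicate(10000, select_parents(c(1, 1, 1, 1)))
    chi <- stats::chisq.test(table(factor(draws, levels = 1:4)))
    expect_gt(chi$p.value, 0.01)

    draws2 <- as.vector(replicate(50000, select_parents(c(0.6, 0.3, 0.1))))
    freq <- as.vector(table(factor(draws2, levels = 1:3))) / length(draws2)
    expect_equal(freq, c(0.6, 0.3, 0.1), tolerance = 0.02)

    # all-zero fitness: documented uniform fallback
    draws3 <- as.vector(replicate(2000, select_parents(c(0, 0, 0))))
    expect_setequal(unique(draws3), 1:3)
  })
  expect_error(select_parents(c(-1, 2)), "non-negative")
})

test_that("crossover preserves size, uniqueness and shared predictors", {
  withr::with_seed(6, {
    a <- letters[1:5]
    kids <- crossover(a, a)
    expect_setequal(kids[[1]], a)
    expect_setequal(kids[[2]], a)

    # property check over many random parent pairs
    pool <- sprintf("F%03d", 1:41)
    violations <- 0L
    for (i in 1:10000) {
      pa <- sample(pool, 8)
      pb <- sample(pool, 8)
      kids <- crossover(pa, pb)
      for (child in kids) {
        ok <- length(child) == 8 &&
          anyDuplicated(child) == 0 &&
          all(child %in% union(pa, pb)) &&
          all(intersect(pa, pb) %in% child)
        if (!ok) violations <- violations + 1L
      }
    }
    expect_equal(violations, 0L)
    # disjoint parents with full exchange are the swapped parents
    full_swap <- FALSE
    for (i in 1:200) {
      kids <- crossover(letters[1:4], letters[5:8])
      if (setequal(kids[[1]], letters[5:8])) {
        expect_setequal(kids[[2]], letters[1:4])
        full_swap <- TRUE
      }
    }
    expect_true(full_swap)
  })
  expect_error(crossover(letters[1:3], letters[1:4]), "equal size")
})

test_that("search space size is exact, including the 41-choose-20 pool", {
  expect_identical(search_space_size(41, 20), 269128937220)
  expect_identical(search_space_size(5, 2), 10)
  expect_identical(search_space_size(7, 0), 1)
  expect_identical(search_space_size(6, 6), 1)
  # beyond the double mantissa: exact decimal string
  expect_identical(search_space_size(100, 50),
                   "100891344545564193334812497256")
  expect_error(search_space_size(5, 6), "exceed")
  expect_error(search_space_size(5.5, 2), "integer")
})

test_that("the GA is elitist-monotone and degenerates correctly at pool = k", {
  sim <- simulate_cell_panel(panel_spec(n_samples = 40, pool_size = 12,
                                        planted_size = 6, effect = 1.5,
                                        seed = 4))
  lab <- dichotomize_sf2(sim$sf2)
  fit <- evolve(sim$expr, lab, sim$expr$probe_id,
                ga_config(population = 20, generations = 12, k = 6,
                          cv_folds = 4, seed = 3))
  expect_false(is.unsorted(fit$trace$best_accuracy))
  expect_equal(nrow(fit$trace), 12)
  expect_length(fit$best_set, 6)

  # same config, same result (seed contract)
  fit2 <- evolve(sim$expr, lab, sim$expr$probe_id,
                 ga_config(population = 20, generations = 12, k = 6,
                           cv_folds = 4, seed = 3))
  expect_identical(fit$trace, fit2$trace)

  # pool size = k: flat trace, best set = pool
  pool12 <- sim$expr$probe_id
  fitk <- evolve(sim$expr, lab, pool12,
                 ga_config(population = 5, generations = 4, k = 12,
                           cv_folds = 4, seed = 1))
  expect_equal(length(unique(fitk$trace$best_accuracy)), 1)
  expect_setequal(fitk$best_set, pool12)

  # broom-style accessors
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$generations, 12)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("permutation p-values follow the add-one formula and never reach 0", {
  sim <- simulate_cell_panel(panel_spec(n_samples = 40, pool_size = 15,
                                        planted_size = 5, effect = 1,
                                        seed = 6))
  lab <- dichotomize_sf2(sim$sf2)
  pt_hi <- permutation_null(sim$expr, lab, sim$expr$probe_id, observed = 1.01,
                            k = 5, n_perm = 999, folds = 4, seed = 2)
  expect_equal(pt_hi$empirical_p, 1 / 1000)
  pt_lo <- permutation_null(sim$expr, lab, sim$expr$probe_id, observed = 0,
                            k = 5, n_perm = 99, folds = 4, seed = 2)
  expect_equal(pt_lo$empirical_p, 1)
  expect_gt(pt_lo$empirical_p, 0)
  expect_s3_class(ggplot2::autoplot(pt_lo), "ggplot")
})

test_that("lncRNA-bearing subsets score higher when only lncRNAs carry signal", {
  # panel where the planted (signal) features are exactly the lncRNA-flagged
  sim <- simulate_cell_panel(panel_spec(n_samples = 60, pool_size = 30,
                                        planted_size = 6, effect = 1.5,
                                        seed = 9))
  lab <- dichotomize_sf2(sim$sf2)
  ann <- tibble::tibble(probe_id = sim$expr$probe_id,
                        biotype = ifelse(sim$expr$probe_id %in%
                                           sim$truth$planted, "lncRNA", "gene"))
  pt <- permutation_null(sim$expr, lab, sim$expr$probe_id, observed = 1,
                         k = 4, n_perm = 400, folds = 5, seed = 3)
  cmp <- compare_biotype_contribution(pt, ann)
  with_l <- cmp$mean_accuracy[cmp$group == "with_lncRNA"]
  without_l <- cmp$mean_accuracy[cmp$group == "without_lncRNA"]
  has <- vapply(pt$sets, function(s) any(s %in% sim$truth$planted), TRUE)
  tt <- stats::t.test(pt$null[has], pt$null[!has], alternative = "greater")
  expect_gt(with_l, without_l)
  expect_lt(tt$p.value, 0.01)
})

test_that("under the global null the GA does not manufacture significance", {
  sim <- simulate_cell_panel(panel_spec(n_samples = 60, pool_size = 41,
                                        planted_size = 20, effect = 0,
                                        seed = 14))
  lab <- dichotomize_sf2(sim$sf2)
  cfg <- ga_config(population = 10, generations = 3, k = 20, cv_folds = 5,
                   seed = 8)
  fit <- evolve(sim$expr, lab, sim$expr$probe_id, cfg)
  y <- align_labels(sim$expr, lab)
  folds <- make_cv_folds(y, 5, fold_seed = derive_seed(cfg$seed, "cv_folds"))
  pt <- permutation_null(sim$expr, lab, sim$expr$probe_id,
                         observed = fit$best_accuracy, k = 20, n_perm = 1000,
                         folds = folds, seed = 15)
  expect_gt(pt$empirical_p, 0.01)
})
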