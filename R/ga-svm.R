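#' Dichotomize SF2 into radiosensitive / radioresistant labels
#'
#' SF2 (surviving fraction after 2 Gy) at or below the threshold marks a
#' radiosensitive (RS) line; above it, radioresistant (RR). The boundary
#' value itself is RS.
#'
#' @param sf2 Tibble with `sample_id` and `sf2` columns, or a named
#'   numeric vector.
#' @param threshold SF2 cut point (default 0.4).
#' @return Tibble: `sample_id`, `label` (factor with levels RR, RS).
#' @export
dichotomize_sf2 <- function(sf2, threshold = 0.4) {
  if (is.data.frame(sf2)) {
    stopifnot(all(c("sample_id", "sf2") %in% names(sf2)))
    ids <- sf2$sample_id
    v <- sf2$sf2
  } else {
    ids <- names(sf2) %||% as.character(seq_along(sf2))
    v <- unname(sf2)
  }
  if (any(v <= 0 | v > 1)) abort("SF2 values must lie in (0, 1]")
  tibble(sample_id = ids,
         label = factor(ifelse(v <= threshold, "RS", "RR"),
                        levels = c("RR", "RS")))
}

align_labels <- function(expr, labels) {
  sam <- names(expr)[-1]
  if (is.data.frame(labels)) {
    y <- labels$label[match(sam, labels$sample_id)]
  } else {
    y <- labels[sam]
  }
  if (anyNA(y)) abort("labels missing for some samples")
  factor(as.character(y), levels = c("RR", "RS"))
}

#' Build a stratified cross-validation fold partition
#'
#' The partition is fixed by `fold_seed` and intended to be reused for
#' every predictor set scored in one run, so fitness values are
#' comparable. When a class has fewer members than `folds`, the fold count
#' is reduced to that class size with a warning.
#'
#' @param y Factor of class labels, one per sample.
#' @param folds Requested fold count.
#' @param fold_seed Integer seed fixing the partition.
#' @return List of integer vectors of test-set sample indices.
#' @export
make_cv_folds <- function(y, folds = 5, fold_seed = 1L) {
  n <- length(y)
  if (folds > n) abort("more folds than samples")
  if (folds < 2) abort("need at least 2 folds")
  min_class <- min(table(y))
  if (min_class < 1) abort("both classes must be present")
  if (min_class < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    folds, min_class))
    folds <- min_class
  }
  withr::with_seed(fold_seed, {
    fold_of <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    lapply(seq_len(folds), function(f) which(fold_of == f))
  })
}

# Pooled CV accuracy of a linear SVM on the columns `cols` of the
# samples-x-features matrix `x`. Features are standardized with
# training-fold mean/SD inside each fold.
svm_cv_accuracy <- function(x, y, cols, fold_list) {
  correct <- 0L
  for (test_idx in fold_list) {
    tr <- x[-test_idx, cols, drop = FALSE]
    te <- x[test_idx, cols, drop = FALSE]
    nt <- nrow(tr)
    mu <- colMeans(tr)
    sdv <- sqrt(pmax(colSums(tr^2) - nt * mu^2, 0) / (nt - 1))
    sdv[sdv == 0] <- 1
    tr_z <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
    te_z <- sweep(sweep(te, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(x = tr_z, y = y[-test_idx], kernel = "linear",
                      cost = 1, scale = FALSE)
    pred <- stats::predict(fit, te_z)
    correct <- correct + sum(pred == y[test_idx])
  }
  correct / length(y)
}

#' Cross-validated linear-SVM accuracy of a predictor set
#'
#' Scores a predictor set by stratified k-fold cross-validation: within
#' each fold, features are standardized by the training-fold mean/SD, a
#' linear-kernel SVM (cost 1) is fit on the training folds, and the pooled
#' fraction of correct test-fold predictions is returned. With a fixed
#' fold partition this is a deterministic function of the data, labels
#' and set, which is what makes GA fitness values comparable.
#'
#' @param expr Panel expression tibble (`probe_id` + sample columns).
#' @param labels Output of [dichotomize_sf2()] (or a named factor).
#' @param predictor_set Character vector of probe ids to use as features.
#' @param folds Fold count, or a precomputed fold list from
#'   [make_cv_folds()].
#' @param fold_seed Seed fixing the partition when `folds` is a count.
#' @return Pooled accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(expr, labels, predictor_set, folds = 5, fold_seed = 1L) {
  validate_expr(expr, min_samples = 4)
  y <- align_labels(expr, labels)
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present")
  missing <- setdiff(predictor_set, expr$probe_id)
  if (length(missing)) {
    abort(paste0("predictor probes absent from expression: ",
                 paste(missing, collapse = ", ")))
  }
  x <- t(expr_to_matrix(expr))
  fold_list <- if (is.list(folds)) folds else make_cv_folds(y, folds, fold_seed)
  svm_cv_accuracy(x, y, predictor_set, fold_list)
}

#' Genetic-algorithm configuration
#'
#' @param population Chromosomes per generation (default 100).
#' @param generations Generations to evolve (default 100).
#' @param k Predictors per chromosome (default 20).
#' @param cv_folds Cross-validation folds for the fitness (default 5).
#' @param seed Integer seed for the whole run (initial population,
#'   roulette selection, crossover, and the CV fold partition).
#' @param elitism Best chromosomes carried forward unchanged (default 1).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 100, generations = 100, k = 20,
                      cv_folds = 5, seed = 1L, elitism = 1) {
  spec <- list(population = population, generations = generations, k = k,
               cv_folds = cv_folds, seed = as.integer(seed), elitism = elitism)
  for (f in c("population", "generations", "k", "cv_folds", "elitism")) {
    check_positive_count(spec[[f]], f)
  }
  if (spec$population < 2) abort("population must be >= 2")
  if (spec$cv_folds < 2) abort("cv_folds must be >= 2")
  structure(spec, class = "ga_config")
}

#' Draw the initial GA population
#'
#' Each chromosome is a uniform random k-subset of the candidate pool;
#' duplicate chromosomes across the population are allowed.
#'
#' @param pool Candidate probe ids.
#' @param config A [ga_config()].
#' @return List of `population` character vectors of length `k`.
#' @export
init_population <- function(pool, config) {
  if (length(pool) < config$k) abort("pool smaller than chromosome size k")
  lapply(seq_len(config$population), function(i) sample(pool, config$k))
}

#' Roulette-wheel parent selection
#'
#' Draws two population indices independently with probability
#' proportional to fitness (`p_i = acc_i / sum(acc)`); the draws may
#' coincide. All-zero fitness falls back to uniform selection.
#'
#' @param fitness Non-negative fitness vector.
#' @return Integer vector of two indices.
#' @export
select_parents <- function(fitness) {
  if (any(fitness < 0)) abort("fitness must be non-negative")
  if (sum(fitness) == 0) fitness <- rep(1, length(fitness))
  sample.int(length(fitness), 2, replace = TRUE, prob = fitness / sum(fitness))
}

#' Crossover of two fixed-size predictor sets
#'
#' Predictors shared by both parents are always retained. Among the
#' symmetric difference, a uniform random number `m` of predictors
#' (from 0 to the number of parent-specific predictors) is exchanged
#' between the parents, so children keep exactly `k` members with no
#' duplicates.
#'
#' @param a,b Parent chromosomes (equal-length probe id vectors).
#' @return List of two children.
#' @export
crossover <- function(a, b) {
  if (length(a) != length(b)) abort("parents must have equal size")
  d_a <- setdiff(a, b)
  d_b <- setdiff(b, a)
  shared <- intersect(a, b)
  m <- sample.int(length(d_a) + 1L, 1) - 1L
  swap_a <- if (m > 0) sample(d_a, m) else character()
  swap_b <- if (m > 0) sample(d_b, m) else character()
  child1 <- c(shared, setdiff(d_a, swap_a), swap_b)
  child2 <- c(shared, setdiff(d_b, swap_b), swap_a)
  list(child1, child2)
}

#' Evolve a predictor set by genetic-algorithm search
#'
#' Each generation scores every chromosome by [cv_accuracy()] on one fixed
#' fold partition, carries the best chromosome forward unchanged
#' (elitism), and fills the rest of the population with crossover children
#' of roulette-selected parents. Fitness values are cached by chromosome,
#' so converged populations cost little to rescore.
#'
#' @param expr Panel expression tibble.
#' @param labels Output of [dichotomize_sf2()].
#' @param pool Candidate probe ids (the predictor pool).
#' @param config A [ga_config()].
#' @return Object of class `ga_fit`: `trace` (tibble: `generation`,
#'   `best_accuracy`, `mean_accuracy`, `best_set` list-column),
#'   `best_set`, `best_accuracy`, `folds`, `config`, `n_evaluations`.
#' @export
evolve <- function(expr, labels, pool, config = ga_config()) {
  validate_expr(expr, min_samples = 4)
  y <- align_labels(expr, labels)
  if (length(pool) < config$k) abort("pool smaller than chromosome size k")
  x <- t(expr_to_matrix(expr))

  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  withr::with_seed(config$seed, {
    fold_list <- make_cv_folds(y, config$cv_folds,
                               fold_seed = derive_seed(config$seed, "cv_folds"))
    fitness_of <- function(set) {
      key <- paste(sort(set), collapse = "|")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      acc <- svm_cv_accuracy(x, y, set, fold_list)
      cache[[key]] <- acc
      n_evals <<- n_evals + 1L
      acc
    }

    pop <- init_population(pool, config)
    trace <- vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      fit <- vapply(pop, fitness_of, 0)
      best_i <- which.max(fit)
      trace[[gen]] <- tibble(generation = gen,
                             best_accuracy = fit[best_i],
                             mean_accuracy = mean(fit),
                             best_set = list(sort(pop[[best_i]])))
      if (gen == config$generations) break
      elite <- pop[order(-fit)[seq_len(config$elitism)]]
      children <- list()
      while (length(children) < config$population - config$elitism) {
        par <- select_parents(fit)
        kids <- crossover(pop[[par[1]]], pop[[par[2]]])
        children <- c(children, kids)
      }
      pop <- c(elite, children[seq_len(config$population - config$elitism)])
    }
  })
  trace <- dplyr::bind_rows(trace)
  best_gen <- which.max(trace$best_accuracy)
  structure(list(trace = trace,
                 best_set = trace$best_set[[best_gen]],
                 best_accuracy = trace$best_accuracy[best_gen],
                 folds = NULL,
                 config = config,
                 n_evaluations = n_evals),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("GA predictor search: %d generations, population %d, k = %d\n",
              nrow(x$trace), x$config$population, x$config$k))
  cat(sprintf("best CV accuracy %.3f (%d distinct sets evaluated)\n",
              x$best_accuracy, x$n_evaluations))
  invisible(x)
}

#' @rdname evolve
#' @param x A `ga_fit` object.
#' @param ... Unused.
#' @method tidy ga_fit
#' @export
tidy.ga_fit <- function(x, ...) x$trace

#' @rdname evolve
#' @method glance ga_fit
#' @export
glance.ga_fit <- function(x, ...) {
  tibble(best_accuracy = x$best_accuracy,
         final_best_accuracy = x$trace$best_accuracy[nrow(x$trace)],
         generations = nrow(x$trace),
         population = x$config$population,
         k = x$config$k,
         n_evaluations = x$n_evaluations)
}

#' @rdname evolve
#' @param object A `ga_fit` object.
#' @method autoplot ga_fit
#' @export
autoplot.ga_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace[c("generation", "best_accuracy",
                                           "mean_accuracy")],
                            -"generation",
                            names_to = "series", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$accuracy,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "5-fold CV accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Exact size of the k-subset search space
#'
#' Exact binomial coefficient `choose(pool_size, k)`, computed with
#' arbitrary-precision integer arithmetic so results beyond the double
#' mantissa stay exact.
#'
#' @param pool_size Pool size.
#' @param k Subset size.
#' @return A double when the result is below 2^53, otherwise its exact
#'   decimal representation as a character string.
#' @export
search_space_size <- function(pool_size, k) {
  if (k < 0 || pool_size < 0 || k != round(k) || pool_size != round(pool_size)) {
    abort("pool_size and k must be non-negative integers")
  }
  if (k > pool_size) abort("k must not exceed pool_size")
  # bignum: little-endian vector of base-1e7 digits
  big_mul <- function(x, s) {
    carry <- 0
    for (i in seq_along(x)) {
      v <- x[i] * s + carry
      x[i] <- v %% 1e7
      carry <- v %/% 1e7
    }
    while (carry > 0) {
      x <- c(x, carry %% 1e7)
      carry <- carry %/% 1e7
    }
    x
  }
  big_div <- function(x, s) { # exact division
    rem <- 0
    for (i in rev(seq_along(x))) {
      v <- rem * 1e7 + x[i]
      x[i] <- v %/% s
      rem <- v %% s
    }
    stopifnot(rem == 0)
    while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
    x
  }
  r <- 1
  for (i in seq_len(min(k, pool_size - k))) {
    r <- big_mul(r, pool_size - min(k, pool_size - k) + i)
    r <- big_div(r, i)
  }
  as_string <- paste0(r[length(r)],
                      paste(sprintf("%07d", rev(r[-length(r)])), collapse = ""))
  value <- sum(r * 1e7^(seq_along(r) - 1))
  if (value < 2^53) value else as_string
}

#' Permutation null for a predictor set's CV accuracy
#'
#' Draws `n_perm` uniform random k-subsets of the candidate pool, scores
#' each with the same cross-validation partition used for the observed
#' model, and computes the add-one empirical p-value
#' `(#\{null >= observed\} + 1) / (n_perm + 1)`, which can never be zero.
#'
#' @param expr Panel expression tibble.
#' @param labels Output of [dichotomize_sf2()].
#' @param pool Candidate probe ids.
#' @param observed Observed accuracy to rank (e.g. the GA's best).
#' @param k Subset size (default 20).
#' @param n_perm Null draws (default 1000).
#' @param folds Fold count or precomputed fold list; must match the
#'   observed model's partition for a fair comparison.
#' @param fold_seed Seed fixing the partition when `folds` is a count.
#' @param seed Seed for the null draws.
#' @return Object of class `perm_test`: `null` (accuracies), `sets`
#'   (list of drawn subsets), `observed`, `empirical_p`, `k`, `n_perm`.
#' @export
permutation_null <- function(expr, labels, pool, observed, k = 20,
                             n_perm = 1000, folds = 5, fold_seed = 1L,
                             seed = 1L) {
  check_positive_count(n_perm, "n_perm")
  validate_expr(expr, min_samples = 4)
  y <- align_labels(expr, labels)
  x <- t(expr_to_matrix(expr))
  fold_list <- if (is.list(folds)) folds else make_cv_folds(y, folds, fold_seed)
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_perm), function(i) sample(pool, k))
  })
  null <- vapply(sets, function(s) svm_cv_accuracy(x, y, s, fold_list), 0)
  structure(list(null = null, sets = sets, observed = observed,
                 empirical_p = (sum(null >= observed) + 1) / (n_perm + 1),
                 k = k, n_perm = n_perm),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation null: %d draws of %d predictors; observed %.3f; empirical p = %.4g\n",
    x$n_perm, x$k, x$observed, x$empirical_p))
  invisible(x)
}

#' @rdname permutation_null
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(draw = seq_along(x$null), accuracy = x$null)
}

#' @rdname permutation_null
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(observed = x$observed, empirical_p = x$empirical_p,
         n_perm = x$n_perm, null_mean = mean(x$null), null_max = max(x$null))
}

#' @rdname permutation_null
#' @param object A `perm_test` object.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "null CV accuracy", y = "draws") +
    ggplot2::theme_minimal()
}

#' Mean null accuracy with and without lncRNA predictors
#'
#' Splits the permutation-null draws by whether the drawn subset contains
#' at least one lncRNA probe and reports each group's mean accuracy — the
#' comparison used to ask whether adding lncRNAs to the candidate pool
#' improves prediction.
#'
#' @param result A `perm_test` from [permutation_null()].
#' @param annotation Annotation tibble with `probe_id` and `biotype`.
#' @return Tibble: `group` (`"with_lncRNA"`/`"without_lncRNA"`), `n`,
#'   `mean_accuracy`.
#' @export
compare_biotype_contribution <- function(result, annotation) {
  lnc <- annotation$probe_id[annotation$biotype == "lncRNA"]
  has_lnc <- vapply(result$sets, function(s) any(s %in% lnc), TRUE)
  tibble(
    group = c("with_lncRNA", "without_lncRNA"),
    n = c(sum(has_lnc), sum(!has_lnc)),
    mean_accuracy = c(mean(result$null[has_lnc]), mean(result$null[!has_lnc]))
  )
}
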