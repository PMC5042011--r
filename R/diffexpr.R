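#' One-way ANOVA across time groups, per probe
#'
#' Computes the classical one-way fixed-effects F test for every probe:
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of freedom.
#' Vectorized over probes, so it scales to full arrays.
#'
#' @param expr Expression tibble (`probe_id` + sample columns, log2 scale).
#' @param groups Sample-to-group assignment: either a metadata tibble with
#'   `sample_id` and `group` columns, or a named character vector.
#' @return Tibble: `probe_id`, `f_stat`, `p_anova`.
#' @export
anova_oneway <- function(expr, groups) {
  validate_expr(expr, min_samples = 2)
  g <- group_vector(expr, groups)
  m <- expr_to_matrix(expr)
  check_group_sizes(g)
  lev <- unique(g)
  k <- length(lev)
  n_tot <- length(g)

  group_means <- matrix(vapply(lev, function(l) rowMeans(m[, g == l, drop = FALSE]),
                               numeric(nrow(m))), nrow(m), k)
  n_g <- vapply(lev, function(l) sum(g == l), 0L)
  grand <- rowMeans(m)
  ss_between <- as.vector(group_means^2 %*% n_g) - n_tot * grand^2
  ss_total <- rowSums(m^2) - n_tot * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)

  ms_b <- ss_between / (k - 1)
  ms_w <- ss_within / (n_tot - k)
  f <- ifelse(ms_w == 0, ifelse(ms_b == 0, 0, Inf), ms_b / ms_w)
  p <- ifelse(ms_w == 0 & ms_b == 0, 1,
              stats::pf(f, k - 1, n_tot - k, lower.tail = FALSE))
  tibble(probe_id = rownames(m), f_stat = unname(f), p_anova = unname(p))
}

check_group_sizes <- function(g) {
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste0("groups with < 2 samples: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  invisible(sizes)
}

contrast_parts <- function(contrast) {
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort(paste0("unknown contrast: ", contrast))
  parts # c(b, a): contrast is b vs a
}

#' Tukey HSD pairwise comparisons, per probe
#'
#' For every pair of groups, the mean difference is referred to the
#' studentized-range distribution with `k` groups and `N - k` residual
#' degrees of freedom, using the pooled within-group variance
#' (Tukey-Kramer form for unequal group sizes).
#'
#' @inheritParams anova_oneway
#' @return Tibble: `probe_id`, `contrast` (e.g. `"2h_vs_0h"`), `p_tukey`.
#' @export
tukey_hsd <- function(expr, groups) {
  validate_expr(expr, min_samples = 2)
  g <- group_vector(expr, groups)
  m <- expr_to_matrix(expr)
  check_group_sizes(g)
  lev <- sort(unique(g))
  k <- length(lev)
  n_tot <- length(g)

  group_means <- matrix(vapply(lev, function(l) rowMeans(m[, g == l, drop = FALSE]),
                               numeric(nrow(m))), nrow(m), k)
  n_g <- vapply(lev, function(l) sum(g == l), 0L)
  ss_within <- rowSums(matrix(vapply(lev, function(l) {
    x <- m[, g == l, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  }, numeric(nrow(m))), nrow(m), k))
  ms_w <- ss_within / (n_tot - k)

  combos <- utils::combn(seq_len(k), 2)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    i1 <- combos[1, j]; i2 <- combos[2, j]
    se <- sqrt(ms_w / 2 * (1 / n_g[i1] + 1 / n_g[i2]))
    q <- abs(group_means[, i2] - group_means[, i1]) / se
    p <- ifelse(se == 0, 1,
                stats::ptukey(q, nmeans = k, df = n_tot - k, lower.tail = FALSE))
    tibble(probe_id = rownames(m),
           contrast = paste0(lev[i2], "_vs_", lev[i1]),
           p_tukey = unname(pmin(p, 1)))
  })
  res
}

#' Linear-scale fold change between two groups
#'
#' Expression is assumed log2, so the fold change is the geometric-mean
#' ratio `2^(mean_log2(b) - mean_log2(a))` for contrast `"b_vs_a"`.
#'
#' @inheritParams anova_oneway
#' @param contrast Contrast string such as `"2h_vs_0h"`; both group labels
#'   must occur in `groups`.
#' @return Tibble: `probe_id`, `contrast`, `fc` (linear scale, > 0).
#' @export
fold_change <- function(expr, groups, contrast) {
  validate_expr(expr)
  g <- group_vector(expr, groups)
  parts <- contrast_parts(contrast)
  if (!all(parts %in% g)) abort(paste0("unknown contrast: ", contrast))
  m <- expr_to_matrix(expr)
  d <- rowMeans(m[, g == parts[1], drop = FALSE]) -
    rowMeans(m[, g == parts[2], drop = FALSE])
  tibble(probe_id = rownames(m), contrast = contrast, fc = unname(2^d))
}

#' Run the full differential-expression screen
#'
#' Combines [anova_oneway()], [tukey_hsd()] and [fold_change()] into one
#' wide per-probe table for the two 0h-referenced contrasts plus 6h vs 2h.
#'
#' @inheritParams anova_oneway
#' @return Tibble: `probe_id`, `f_stat`, `p_anova`, then `p_tukey` and `fc`
#'   columns per contrast (`p_2h_vs_0h`, `fc_2h_vs_0h`, ...).
#' @export
run_diffexpr <- function(expr, groups) {
  an <- anova_oneway(expr, groups)
  tk <- tukey_hsd(expr, groups) |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "p_tukey",
                       names_prefix = "p_")
  g <- group_vector(expr, groups)
  lev <- sort(unique(g))
  combos <- utils::combn(lev, 2)
  fc <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    fold_change(expr, groups, paste0(combos[2, j], "_vs_", combos[1, j]))
  }) |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "fc",
                       names_prefix = "fc_")
  an |> dplyr::left_join(tk, by = "probe_id") |>
    dplyr::left_join(fc, by = "probe_id")
}

#' Select differentially expressed probes per contrast
#'
#' A probe enters a contrast's significant set when the overall ANOVA p,
#' that contrast's Tukey-adjusted p, and the fold-change filter all pass:
#' `p_anova < alpha`, `p_tukey < alpha`, `max(fc, 1/fc) >= fc_min`. Only
#' the two 0h-referenced contrasts are used for selection; the union set
#' feeds the co-expression stage.
#'
#' @param results Output of [run_diffexpr()].
#' @param annotation Optional annotation tibble; adds lncRNA counts.
#' @param alpha Significance level for both tests (default `1e-4`).
#' @param fc_min Minimum linear fold change in either direction
#'   (default 1.3).
#' @return Object of class `de_selection`: list with `set_2h`, `set_6h`,
#'   `union` (character vectors of probe ids) and `summary` tibble
#'   (per-set sizes and lncRNA counts when annotation is given).
#' @export
select_differential <- function(results, annotation = NULL, alpha = 1e-4,
                                fc_min = 1.3) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (!is.numeric(fc_min) || fc_min < 1) abort("fc_min must be >= 1")
  pick <- function(p_tukey, fc) {
    results$probe_id[results$p_anova < alpha & p_tukey < alpha &
                       pmax(fc, 1 / fc) >= fc_min]
  }
  set_2h <- pick(results$p_2h_vs_0h, results$fc_2h_vs_0h)
  set_6h <- pick(results$p_6h_vs_0h, results$fc_6h_vs_0h)
  union_set <- union(set_2h, set_6h)

  n_lnc <- function(ids) {
    if (is.null(annotation)) return(NA_integer_)
    sum(annotation$biotype[match(ids, annotation$probe_id)] == "lncRNA",
        na.rm = TRUE)
  }
  summary <- tibble(
    set = c("2h_vs_0h", "6h_vs_0h", "union"),
    n_probes = c(length(set_2h), length(set_6h), length(union_set)),
    n_lncRNA = c(n_lnc(set_2h), n_lnc(set_6h), n_lnc(union_set))
  )
  structure(list(set_2h = set_2h, set_6h = set_6h, union = union_set,
                 summary = summary, alpha = alpha, fc_min = fc_min),
            class = "de_selection")
}

#' @export
print.de_selection <- function(x, ...) {
  cat(sprintf("Differential-expression selection (alpha = %g, fc_min = %g)\n",
              x$alpha, x$fc_min))
  print(x$summary)
  invisible(x)
}

#' @rdname select_differential
#' @param x A `de_selection` object.
#' @param ... Unused.
#' @method tidy de_selection
#' @export
tidy.de_selection <- function(x, ...) x$summary

#' @rdname select_differential
#' @method glance de_selection
#' @export
glance.de_selection <- function(x, ...) {
  tibble(n_2h = length(x$set_2h), n_6h = length(x$set_6h),
         n_union = length(x$union), alpha = x$alpha, fc_min = x$fc_min)
}
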