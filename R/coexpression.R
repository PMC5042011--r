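#' Co-expression network configuration
#'
#' @param candidate_powers Soft-threshold exponents to scan (default 1:20).
#' @param rsq_target Scale-free topology fit threshold (default 0.8): the
#'   smallest power whose signed fit reaches this value is chosen.
#' @param min_module_size Minimum probes per retained module (default 30).
#' @param deep_split Tree-cut sensitivity, 0 (coarse) to 3 (fine);
#'   default 3.
#' @param n_bins Bins for the scale-free fit of the connectivity
#'   distribution (default 10).
#' @return A `network_config` list.
#' @export
network_config <- function(candidate_powers = 1:20, rsq_target = 0.8,
                           min_module_size = 30, deep_split = 3, n_bins = 10) {
  if (any(candidate_powers <= 0) || any(candidate_powers != round(candidate_powers))) {
    abort("candidate_powers must be positive integers")
  }
  if (rsq_target <= 0 || rsq_target > 1) abort("rsq_target must lie in (0, 1]")
  if (!deep_split %in% 0:3) abort("deep_split must be 0, 1, 2 or 3")
  check_positive_count(min_module_size, "min_module_size")
  structure(list(candidate_powers = as.integer(candidate_powers),
                 rsq_target = rsq_target,
                 min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 n_bins = as.integer(n_bins)),
            class = "network_config")
}

probe_cor <- function(expr) {
  m <- expr_to_matrix(expr)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("constant probe rows: ",
                 paste(head(rownames(m)[sds == 0], 5), collapse = ", ")))
  }
  stats::cor(t(m))
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `n_bins` equal-width bins, regresses
#' `log10` of the bin frequency on `log10` of the bin-mean connectivity,
#' and reports the fit. The signed fit is `R^2` when the slope is negative
#' (the scale-free direction) and `-R^2` otherwise.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of bins.
#' @return List: `r_squared`, `slope`, `signed_rsq`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.vector(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(kmean) & freq > 0 & kmean > 0
  if (sum(keep) < 2) return(list(r_squared = 0, slope = 0, signed_rsq = 0))
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  slope <- stats::coef(fit)[[2]]
  # summary.lm warns on exact fits, which constructed power laws produce
  rsq <- suppressWarnings(summary(fit)$r.squared)
  list(r_squared = rsq, slope = slope,
       signed_rsq = if (slope < 0) rsq else -rsq)
}

#' Choose the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power, raises the absolute probe-probe Pearson
#' correlation to that power, computes each probe's connectivity
#' `k_i = sum_j |r_ij|^beta`, and evaluates the scale-free fit of the
#' connectivity distribution. The smallest power reaching `rsq_target`
#' wins; when none does, the power with the best signed fit is returned.
#'
#' @param expr Expression tibble (probes as rows).
#' @param config A [network_config()].
#' @return List: `power` (chosen exponent) and `fit` (tibble with one row
#'   per candidate: `power`, `rsq`, `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(expr, config = network_config()) {
  validate_expr(expr, min_samples = 4)
  if (nrow(expr) < 3) abort("need at least 3 probes")
  r <- abs(probe_cor(expr))
  diag(r) <- 0
  fit <- purrr::map_dfr(config$candidate_powers, function(beta) {
    k <- rowSums(r^beta)
    sf <- scale_free_fit(k, config$n_bins)
    tibble(power = beta, rsq = sf$signed_rsq, slope = sf$slope, mean_k = mean(k))
  })
  ok <- fit$power[fit$rsq >= config$rsq_target]
  power <- if (length(ok)) min(ok) else fit$power[which.max(fit$rsq)]
  list(power = power, fit = fit)
}

#' Weighted network adjacency from expression
#'
#' Unsigned adjacency: `a_ij = |cor(i, j)|^power`, unit diagonal.
#'
#' @param expr Expression tibble (probes as rows).
#' @param power Soft-threshold exponent.
#' @return Symmetric adjacency matrix with entries in \[0, 1\].
#' @export
adjacency <- function(expr, power) {
  if (power <= 0) abort("power must be positive")
  a <- abs(probe_cor(expr))^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` over shared neighbours `u != i, j` and
#' `k_i = sum_u a_iu` over `u != i`; `TOM_ii = 1`. High overlap means two
#' probes are strongly connected to the same neighbourhood, which is the
#' similarity used for module detection.
#'
#' @param a Adjacency matrix (square, symmetric, entries in \[0, 1\],
#'   unit diagonal).
#' @return TOM matrix of the same dimension.
#' @export
tom_similarity <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a)) abort("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-12) abort("adjacency must be symmetric")
  if (min(a) < 0 || max(a) > 1) abort("adjacency entries must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  tom <- (l + a0) / (outer(k, k, pmin) + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by hierarchical tree cut
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a height
#' quantile controlled by `deep_split` (higher = deeper cut = more, finer
#' branches). Clusters smaller than `min_module_size` are left unassigned
#' (label 0); retained modules are labelled 1, 2, ... by decreasing size.
#'
#' @param tom TOM matrix (see [tom_similarity()]).
#' @param config A [network_config()].
#' @return Tibble: `probe_id`, `module` (integer, 0 = unassigned).
#' @export
cluster_modules <- function(tom, config = network_config()) {
  probe_ids <- rownames(tom) %||% sprintf("P%05d", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # cut height as a fraction of the deepest merge; deeper splits cut lower
  cut_frac <- c(0.99, 0.97, 0.94, 0.9)[config$deep_split + 1]
  cut_h <- cut_frac * max(hc$height)
  raw <- stats::cutree(hc, h = cut_h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= config$min_module_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  module <- integer(length(raw))
  for (i in seq_along(keep)) module[raw == as.integer(keep[i])] <- i
  tibble(probe_id = probe_ids, module = module)
}

#' Extract highly correlated gene-lncRNA pairs within modules
#'
#' For every lncRNA/gene probe pair assigned to the same (nonzero) module,
#' reports the pair when its Pearson correlation reaches `r_min`.
#'
#' @param expr Expression tibble (probes as rows; the network's input).
#' @param partition Module partition tibble from [cluster_modules()].
#' @param annotation Annotation tibble covering every probe in `expr`.
#' @param r_min Minimum Pearson correlation, inclusive (default 0.75).
#' @param time_label Label recorded in the `time` column (e.g. `"2h"`).
#' @return Pair tibble (`lnc_probe`, `lnc_symbol`, `gene_probe`,
#'   `gene_symbol`, `r`, `time`), sorted by descending correlation.
#' @export
extract_pairs <- function(expr, partition, annotation, r_min = 0.75,
                          time_label = "2h") {
  validate_expr(expr, min_samples = 3)
  missing_ann <- setdiff(expr$probe_id, annotation$probe_id)
  if (length(missing_ann)) {
    abort(paste0("annotation missing probes: ",
                 paste(head(missing_ann, 5), collapse = ", ")))
  }
  mod <- partition$module[match(expr$probe_id, partition$probe_id)]
  if (anyNA(mod)) abort("partition does not cover all probes in expr")
  bio <- annotation$biotype[match(expr$probe_id, annotation$probe_id)]
  sym <- annotation$symbol[match(expr$probe_id, annotation$probe_id)]
  m <- expr_to_matrix(expr)

  out <- purrr::map_dfr(setdiff(unique(mod), 0L), function(k) {
    lnc_i <- which(mod == k & bio == "lncRNA")
    gene_i <- which(mod == k & bio == "gene")
    if (!length(lnc_i) || !length(gene_i)) return(NULL)
    r <- stats::cor(t(m[lnc_i, , drop = FALSE]), t(m[gene_i, , drop = FALSE]))
    hits <- which(r >= r_min, arr.ind = TRUE)
    if (!nrow(hits)) return(NULL)
    tibble(
      lnc_probe = rownames(m)[lnc_i[hits[, 1]]],
      lnc_symbol = sym[lnc_i[hits[, 1]]],
      gene_probe = rownames(m)[gene_i[hits[, 2]]],
      gene_symbol = sym[gene_i[hits[, 2]]],
      r = r[hits],
      time = time_label
    )
  })
  if (nrow(out) == 0) {
    return(tibble(lnc_probe = character(), lnc_symbol = character(),
                  gene_probe = character(), gene_symbol = character(),
                  r = numeric(), time = character()))
  }
  dplyr::arrange(out, dplyr::desc(.data$r))
}

#' Pool candidate predictors from gene-lncRNA pairs
#'
#' Deduplicates the probes appearing in a pair table into a biotype-
#' partitioned candidate pool for feature selection.
#'
#' @param pairs Pair tibble (see [extract_pairs()] / [read_pair_table()]).
#' @return List: `gene` and `lncRNA` (unique probe id vectors) and `pool`
#'   (their union, lncRNA first).
#' @export
pool_predictor_candidates <- function(pairs) {
  lnc <- unique(pairs$lnc_probe)
  gene <- unique(pairs$gene_probe)
  list(gene = gene, lncRNA = lnc, pool = c(lnc, gene))
}
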