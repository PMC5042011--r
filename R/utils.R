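#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Wide expression tibble -> numeric matrix (probes x samples)
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), names(expr)[1] == "probe_id")
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$probe_id
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(probe_id = rownames(m), .before = 1)
}

validate_expr <- function(expr, min_samples = 1) {
  if (!is.data.frame(expr) || names(expr)[1] != "probe_id") {
    abort("`expr` must be a data frame whose first column is `probe_id`.")
  }
  if (anyDuplicated(expr$probe_id)) {
    dup <- unique(expr$probe_id[duplicated(expr$probe_id)])
    abort(paste0("duplicate probe ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  sam <- names(expr)[-1]
  if (anyDuplicated(sam)) abort("duplicate sample ids in expression columns")
  if (length(sam) < min_samples) {
    abort(sprintf("expression matrix needs >= %d sample columns", min_samples))
  }
  m <- expr_to_matrix(expr)
  if (!all(is.finite(m))) abort("expression values must be finite and numeric")
  invisible(expr)
}

# Resolve sample -> group assignment from a metadata tibble.
group_vector <- function(expr, groups, group_col = "group") {
  sam <- names(expr)[-1]
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", group_col) %in% names(groups))) {
      abort(sprintf("`groups` table needs columns sample_id and %s", group_col))
    }
    g <- groups[[group_col]][match(sam, groups$sample_id)]
  } else {
    g <- groups[sam]
  }
  if (anyNA(g)) {
    missing <- sam[is.na(g)]
    abort(paste0("samples missing a group label: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  stats::setNames(as.character(g), sam)
}

# Deterministic per-stage seed derived from a global seed and a stage name.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% (2^31 - 1)) + 1L
}

check_positive_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer", name))
  }
  invisible(as.integer(x))
}
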