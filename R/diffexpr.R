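#' Signed fold change between two groups of log2 values
#'
#' The ratio of geometric means, reported on the signed convention used for
#' annotated gene tables: `r = 2^(mean(case) - mean(control))`, returned as
#' `r` when `r >= 1` and `-1/r` otherwise (so a 4-fold repression is `-4`).
#'
#' @param case_values,control_values per-sample log2 expression vectors.
#' @return signed scalar with `|value| >= 1`.
#' @export
signed_fold_change <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    abort("both groups must be nonempty")
  }
  r <- 2^(mean(case_values) - mean(control_values))
  if (r >= 1) r else -1 / r
}

f_statistics <- function(v, groups) {
  g <- factor(groups)
  n <- ncol(v)
  k <- nlevels(g)
  gm <- rowMeans(v)
  ssb <- numeric(nrow(v))
  ssw <- numeric(nrow(v))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    mi <- rowMeans(v[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (mi - gm)^2
    ssw <- ssw + rowSums((v[, idx, drop = FALSE] - mi)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f)] <- 0
  f
}

#' Multivariate permutation F-test gene selection with FDR confidence
#'
#' Ranks genes by their one-way ANOVA F statistic across sample groups, then
#' chooses the largest top-F set whose false-discovery proportion is bounded
#' by `fdr_target` with the stated confidence: for each candidate set size
#' `m` (F threshold = m-th largest observed F), the number of permuted F
#' values exceeding the threshold is computed in every label permutation, and
#' the set is admissible when the `confidence`-quantile of (permuted
#' exceedances / m) is at most `fdr_target`. With the defaults this is the
#' "maximum FDR of 1% with 80% confidence" selection rule.
#'
#' @param x an [expr_matrix()].
#' @param labels per-sample group labels (>= 2 groups, >= 2 samples each).
#' @param fdr_target maximum tolerated false-discovery proportion.
#' @param confidence probability with which the FDP bound must hold.
#' @param n_permutations number of random label permutations (>= 100).
#' @param rng_seed integer seed for the permutation draws.
#' @return an object of class `de_selection`.
#' @export
permutation_f_select <- function(x, labels, fdr_target = 0.01,
                                 confidence = 0.8, n_permutations = 1000,
                                 rng_seed = 1L) {
  v <- expr_values(x)
  g <- factor(labels)
  if (length(labels) != ncol(v)) abort("one label per sample required")
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("need at least 2 samples per group")
  if (n_permutations < 100) {
    abort("n_permutations must be >= 100 for FDR resolution at the 1% scale")
  }
  f_obs <- f_statistics(v, g)
  names(f_obs) <- rownames(v)
  # stable order: F descending, ties broken by gene id
  ord <- order(-f_obs, rownames(v))
  f_sorted <- f_obs[ord]

  n_genes <- nrow(v)
  counts <- matrix(0L, nrow = n_permutations, ncol = n_genes)
  withr::with_seed(as.integer(rng_seed), {
    for (b in seq_len(n_permutations)) {
      fp <- sort(f_statistics(v, g[sample(ncol(v))]))
      # exceedances of each observed threshold among permuted F values
      counts[b, ] <- n_genes -
        findInterval(f_sorted, fp, left.open = TRUE)
    }
  })
  m_seq <- seq_len(n_genes)
  fdp_q <- vapply(m_seq, function(m) {
    unname(quantile(counts[, m] / m, probs = confidence, type = 1))
  }, numeric(1))
  admissible <- which(fdp_q <= fdr_target & f_sorted > 0)
  m_star <- if (length(admissible) > 0) max(admissible) else 0L
  selected <- if (m_star > 0) names(f_sorted)[seq_len(m_star)] else character(0)
  structure(
    list(
      selected_ids = selected,
      f_statistic = f_obs,
      fdr_target = fdr_target,
      confidence = confidence,
      n_permutations = n_permutations,
      fdp_quantile = stats::setNames(fdp_q, names(f_sorted)),
      rng_seed = as.integer(rng_seed)
    ),
    class = "de_selection"
  )
}

#' @export
print.de_selection <- function(x, ...) {
  cat(sprintf(
    "<de_selection> %d of %d genes at FDR <= %g%% with %g%% confidence (%d permutations)\n",
    length(x$selected_ids), length(x$f_statistic), 100 * x$fdr_target,
    100 * x$confidence, x$n_permutations))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.de_selection <- function(x, ...) {
  tibble::tibble(
    gene_id = names(x$f_statistic),
    f_statistic = unname(x$f_statistic),
    selected = names(x$f_statistic) %in% x$selected_ids
  ) |> dplyr::arrange(dplyr::desc(.data$f_statistic), .data$gene_id)
}

#' @exportS3Method generics::glance
glance.de_selection <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$f_statistic),
    n_selected = length(x$selected_ids),
    fdr_target = x$fdr_target,
    confidence = x$confidence,
    n_permutations = x$n_permutations
  )
}

#' Filter a differential-expression selection by absolute fold change
#'
#' Keeps the selected genes whose `|fold change|` strictly exceeds the
#' threshold (the robustness filter that reduced the motivating study's mRNA
#' list; a gene at exactly the threshold is excluded).
#'
#' @param selection a [permutation_f_select()] result, or a character vector
#'   of gene ids.
#' @param fold_changes named numeric vector of signed fold changes, or a
#'   data frame with `gene_id` and `fold_change` columns.
#' @param threshold strictly positive fold-change cutoff (> 1).
#' @return character vector of retained gene ids, in selection order.
#' @export
fold_change_filter <- function(selection, fold_changes, threshold = 5) {
  if (threshold <= 1) abort("threshold must be > 1")
  ids <- if (inherits(selection, "de_selection")) selection$selected_ids
         else as.character(selection)
  if (is.data.frame(fold_changes)) {
    fold_changes <- stats::setNames(fold_changes$fold_change,
                                    fold_changes$gene_id)
  }
  missing <- setdiff(ids, names(fold_changes))
  if (length(missing) > 0) {
    abort(paste0("missing fold change for selected gene(s): ",
                 paste(missing, collapse = ", ")))
  }
  ids[abs(fold_changes[ids]) > threshold]
}
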