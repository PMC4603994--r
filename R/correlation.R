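#' Kendall tau-b rank correlation
#'
#' Tie-corrected Kendall correlation, `(C - D) / sqrt((n0 - n1) (n0 - n2))`
#' with `C`/`D` the concordant/discordant pair counts and `n1`, `n2` the tied
#' pairs within each margin. Computed in O(n log n) by merge-sort inversion
#' counting. A constant input makes the coefficient undefined; `NA` is
#' returned (never a silent 0).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  .tau_b_cpp(as.numeric(x), as.numeric(y))
}

#' First-order partial Kendall correlation
#'
#' Removes the rank-level association of `x` and `y` with a covariate `z`:
#' `(tau_xy - tau_xz * tau_yz) / sqrt((1 - tau_xz^2) (1 - tau_yz^2))`, each
#' tau being Kendall tau-b. Undefined (returns `NA`) when the covariate is
#' collinear with either variable (`|tau| = 1`) or any input is constant.
#'
#' @param x,y,z numeric vectors of equal length.
#' @return a scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
partial_kendall <- function(x, y, z) {
  if (length(unique(c(length(x), length(y), length(z)))) != 1) {
    abort("x, y and z must have equal length")
  }
  txy <- kendall_tau_b(x, y)
  txz <- kendall_tau_b(x, z)
  tyz <- kendall_tau_b(y, z)
  if (anyNA(c(txy, txz, tyz))) return(NA_real_)
  if (abs(txz) >= 1 - 1e-12 || abs(tyz) >= 1 - 1e-12) return(NA_real_)
  (txy - txz * tyz) / sqrt((1 - txz^2) * (1 - tyz^2))
}

#' Pairwise (partial) Kendall association matrix
#'
#' Computes tau-b for every gene pair of an expression matrix; when a
#' covariate (e.g. per-sample necrosis grade) is supplied, every pairwise tau
#' is replaced by the first-order partial tau with that covariate removed.
#' Undefined pairs (constant genes, covariate collinearity) are recorded in
#' the result and abort by default; `drop_constant = TRUE` removes constant
#' genes before computing.
#'
#' @param x an [expr_matrix()] with at least 4 samples.
#' @param covariate per-sample numeric vector (aligned with the sample
#'   columns) or `NULL` for simple correlations.
#' @param covariate_name label stored in the result.
#' @param drop_constant drop constant gene rows instead of erroring.
#' @return an object of class `assoc_matrix`: list with `gene_ids`,
#'   `species`, `tau` (symmetric matrix, unit diagonal), `mode`
#'   (`"simple"`/`"partial"`) and `covariate_name`.
#' @export
pairwise_matrix <- function(x, covariate = NULL,
                            covariate_name = if (is.null(covariate)) NULL else "covariate",
                            drop_constant = FALSE) {
  v <- expr_values(x)
  if (ncol(v) < 4) abort("need at least 4 samples")
  if (!is.null(covariate)) {
    if (length(covariate) != ncol(v)) {
      abort("covariate must have one value per sample")
    }
    if (anyNA(covariate)) abort("covariate contains missing values")
    if (var(covariate) == 0) {
      abort("constant covariate: partial correlation is undefined")
    }
  }
  const <- apply(v, 1, function(r) all(r == r[1]))
  if (any(const)) {
    if (drop_constant) {
      v <- v[!const, , drop = FALSE]
    } else {
      abort(paste0("constant gene rows make tau undefined: ",
                   paste(rownames(v)[const], collapse = ", "),
                   " (use drop_constant = TRUE to remove them)"))
    }
  }
  tau <- .tau_matrix_cpp(v)
  dimnames(tau) <- list(rownames(v), rownames(v))
  mode <- "simple"
  if (!is.null(covariate)) {
    tz <- .tau_vs_vector_cpp(v, as.numeric(covariate))
    if (any(abs(tz) >= 1 - 1e-12, na.rm = TRUE)) {
      bad <- rownames(v)[which(abs(tz) >= 1)]
      abort(paste0("covariate collinear with gene(s): ",
                   paste(bad, collapse = ", ")))
    }
    den <- sqrt(outer(1 - tz^2, 1 - tz^2))
    tau <- (tau - outer(tz, tz)) / den
    diag(tau) <- 1
    mode <- "partial"
  }
  undef <- which(is.na(tau[upper.tri(tau)]))
  sp <- expr_species(x)[rownames(v)]
  structure(
    list(gene_ids = rownames(v), species = unname(sp), tau = tau,
         mode = mode,
         covariate_name = covariate_name,
         n_undefined_pairs = length(undef)),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d genes, mode=%s%s\n", length(x$gene_ids),
              x$mode,
              if (is.null(x$covariate_name)) "" else
                paste0(" (covariate: ", x$covariate_name, ")")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.assoc_matrix <- function(x, ...) {
  ut <- upper.tri(x$tau)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    gene_a = x$gene_ids[idx[, 1]],
    gene_b = x$gene_ids[idx[, 2]],
    species_a = x$species[idx[, 1]],
    species_b = x$species[idx[, 2]],
    tau = x$tau[ut]
  )
}

upper_taus <- function(assoc) assoc$tau[upper.tri(assoc$tau)]

#' Sarle's bimodality coefficient
#'
#' `(skewness^2 + 1) / kurtosis` with plain (non-excess) moment estimators;
#' the uniform distribution scores exactly 5/9, the conventional benchmark
#' above which a sample is flagged bimodal.
#'
#' @param x numeric vector.
#' @return scalar in `(0, 1]`.
#' @export
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2
  (skew^2 + 1) / kurt
}

#' Distribution profile of pairwise correlations
#'
#' Histogram, kernel density estimate and Sarle's bimodality coefficient over
#' the strict upper triangle of an association matrix — the diagnostic that
#' distinguishes the bimodal raw-correlation distribution of confounded
#' diseased samples from the unimodal control (and covariate-adjusted)
#' distributions.
#'
#' @param assoc an `assoc_matrix`.
#' @param n_bins histogram bin count over `[-1, 1]`.
#' @param bandwidth KDE bandwidth (`stats::density` `bw`); `NULL` for the
#'   default rule.
#' @return a list of class `tau_profile` with `breaks`, `counts`, `density`
#'   (tibble grid/value), `bimodality_coefficient` and `bimodal` flag.
#' @export
distribution_profile <- function(assoc, n_bins = 50, bandwidth = NULL) {
  taus <- upper_taus(assoc)
  if (length(taus) < 3) abort("need at least 3 genes")
  if (anyNA(taus)) abort("association matrix contains undefined pairs")
  h <- hist(taus, breaks = seq(-1, 1, length.out = n_bins + 1), plot = FALSE)
  d <- if (is.null(bandwidth)) stats::density(taus, n = 512) else
    stats::density(taus, bw = bandwidth, n = 512)
  bc <- bimodality_coefficient(taus)
  structure(
    list(
      breaks = h$breaks, counts = h$counts,
      density = tibble::tibble(tau = d$x, density = d$y),
      bimodality_coefficient = bc,
      bimodal = is.finite(bc) && bc > 5 / 9,
      n_pairs = length(taus)
    ),
    class = "tau_profile"
  )
}

#' @export
print.tau_profile <- function(x, ...) {
  cat(sprintf("<tau_profile> %d pairs, bimodality coefficient %.3f (%s)\n",
              x$n_pairs, x$bimodality_coefficient,
              if (x$bimodal) "bimodal" else "unimodal"))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.tau_profile <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    bimodality_coefficient = x$bimodality_coefficient,
    bimodal = x$bimodal
  )
}
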