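#' Transform an association matrix into nonmetric distances
#'
#' Applies the zero-centering transform `d = (-1) * tau` (rather than
#' `1 - tau`), so strongly positively correlated genes are maximally close
#' (`-1`) and strongly anti-correlated genes maximally distant (`+1`).
#'
#' @param assoc an `assoc_matrix` from [pairwise_matrix()].
#' @return an object of class `dist_matrix` with elements `gene_ids`,
#'   `species`, `d` (symmetric, diagonal `-1`) and `provenance`.
#' @export
to_distance <- function(assoc) {
  if (!inherits(assoc, "assoc_matrix")) abort("expected an assoc_matrix")
  if (anyNA(assoc$tau)) {
    abort("association matrix contains undefined pairs; resolve them first")
  }
  structure(
    list(gene_ids = assoc$gene_ids, species = assoc$species,
         d = -assoc$tau,
         provenance = list(mode = assoc$mode,
                           covariate_name = assoc$covariate_name)),
    class = "dist_matrix"
  )
}

new_ordination <- function(gene_ids, species, coordinates, singular_values,
                           method, stress = NA_real_, axis_sign = NULL,
                           converged = TRUE) {
  k <- ncol(coordinates)
  colnames(coordinates) <- paste0("dim", seq_len(k))
  rownames(coordinates) <- gene_ids
  structure(
    list(gene_ids = gene_ids, species = species,
         coordinates = coordinates,
         singular_values = singular_values,
         k_retained = k, method = method, stress = stress,
         axis_sign = axis_sign, converged = converged),
    class = "ordination"
  )
}

# orientation convention: flip each axis so its largest-magnitude loading
# is positive (reproducible across runs and platforms)
orient_axes <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Classical multidimensional scaling by singular value decomposition
#'
#' Recovers the similarity matrix `S = -d` (the Kendall correlations, unit
#' diagonal), double-centers it (`B = J S J` with `J = I - 11'/n`), and
#' factorizes `B` by SVD; coordinates are the left singular vectors scaled by
#' the square roots of the singular values. SVD keeps the factorization
#' numerically stable under the heavy multicollinearity typical of
#' co-expression matrices. Because the input is nonmetric, `B` may have
#' negative eigendirections; their magnitudes enter the singular values and
#' the per-axis sign pattern is reported in `axis_sign` so heavily
#' non-Euclidean structure is detectable.
#'
#' @param dist a `dist_matrix` from [to_distance()].
#' @param k number of dimensions to retain (`1 <= k < n`).
#' @return an object of class `ordination`; coordinates are deterministic, the
#'   per-axis sign fixed by making the largest-magnitude loading positive.
#' @export
classical_scaling_svd <- function(dist, k = 3) {
  d <- dist$d
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("distance matrix is not symmetric")
  }
  if (k < 1 || k >= n) abort("k must satisfy 1 <= k < n")
  s <- -d
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% s %*% j
  b <- (b + t(b)) / 2
  sv <- svd(b)
  # for symmetric B, U and V columns agree up to the eigenvalue sign
  axis_sign <- round(colSums(sv$u * sv$v))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(k)]), k, k)
  coords <- orient_axes(coords)
  new_ordination(dist$gene_ids, dist$species, coords, sv$d,
                 method = "classical_svd",
                 axis_sign = axis_sign[seq_len(k)])
}

#' Reconstruct the double-centered similarity from an ordination
#'
#' `C diag(axis_sign) C'` over the retained axes; at full rank this equals
#' the double-centered similarity matrix to machine precision.
#'
#' @param ord a classical-SVD `ordination`.
#' @return a symmetric matrix.
#' @export
reconstruct_similarity <- function(ord) {
  if (ord$method != "classical_svd") {
    abort("reconstruction is defined for classical_svd ordinations")
  }
  c_ <- ord$coordinates
  c_ %*% diag(ord$axis_sign, ncol(c_), ncol(c_)) %*% t(c_)
}

# Sammon/Kruskal work on positive dissimilarities: shift the zero-centered
# distances uniformly (rank-preserving) and nudge off the zero boundary.
shifted_dissimilarity <- function(d) {
  off <- d[upper.tri(d)]
  dd <- d
  if (min(off) <= 0) {
    eps <- 1e-4 * (max(off) - min(off) + 1e-12)
    dd <- d - min(off) + eps
  }
  diag(dd) <- 0
  stats::as.dist(dd)
}

#' Sammon mapping of a nonmetric distance matrix
#'
#' Iterative minimization of Sammon stress, initialized from the classical
#' SVD configuration (which also makes the result deterministic). Distances
#' are shifted uniformly to positivity first; the shift is monotone, which is
#' all a nonmetric embedding uses.
#'
#' @param dist a `dist_matrix`.
#' @param k dimensions.
#' @param max_iter,tol iteration controls passed to the optimizer.
#' @param rng_seed kept for interface symmetry; the method is deterministic
#'   from its initialization.
#' @return an `ordination` with `stress` filled in and a `converged` flag.
#' @export
sammon_mapping <- function(dist, k = 3, max_iter = 100, tol = 1e-4,
                           rng_seed = 1L) {
  init <- classical_scaling_svd(dist, k)$coordinates
  dd <- shifted_dissimilarity(dist$d)
  fit <- withr::with_seed(as.integer(rng_seed), {
    utils::capture.output(
      res <- MASS::sammon(dd, y = init, k = k, niter = max_iter, tol = tol)
    )
    res
  })
  converged <- TRUE
  new_ordination(dist$gene_ids, dist$species, orient_axes(fit$points),
                 singular_values = numeric(0), method = "sammon",
                 stress = fit$stress, converged = converged)
}

#' Kruskal's nonmetric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 with monotone regression on disparities,
#' initialized from the classical SVD configuration. Stress is reported on
#' the `[0, 1]` scale.
#'
#' @inheritParams sammon_mapping
#' @return an `ordination` with `stress` in `[0, 1]`.
#' @export
kruskal_nmds <- function(dist, k = 3, max_iter = 100, tol = 1e-4,
                         rng_seed = 1L) {
  init <- classical_scaling_svd(dist, k)$coordinates
  dd <- shifted_dissimilarity(dist$d)
  fit <- withr::with_seed(as.integer(rng_seed), {
    utils::capture.output(
      res <- MASS::isoMDS(dd, y = init, k = k, maxit = max_iter, tol = tol)
    )
    res
  })
  new_ordination(dist$gene_ids, dist$species, orient_axes(fit$points),
                 singular_values = numeric(0), method = "kruskal",
                 stress = fit$stress / 100, converged = TRUE)
}

#' Procrustes agreement between two ordination configurations
#'
#' Aligns configuration `b` to `a` by optimal translation, rotation,
#' reflection and scaling, and returns the Procrustes correlation
#' `sqrt(1 - ss / total)` in `[0, 1]` (1 = identical shapes).
#'
#' @param a,b `ordination` objects over the same genes with the same `k`.
#' @return scalar Procrustes correlation.
#' @export
configuration_agreement <- function(a, b) {
  if (!setequal(a$gene_ids, b$gene_ids)) abort("gene sets differ")
  if (a$k_retained != b$k_retained) abort("dimensionalities differ")
  xb <- b$coordinates[a$gene_ids, , drop = FALSE]
  pr <- vegan::procrustes(a$coordinates, xb, symmetric = TRUE)
  sqrt(max(0, 1 - pr$ss))
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d genes, k=%d, method=%s%s\n",
              length(x$gene_ids), x$k_retained, x$method,
              if (is.na(x$stress)) "" else sprintf(", stress=%.4f", x$stress)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ordination <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = x$gene_ids, species = x$species),
    tibble::as_tibble(x$coordinates)
  )
}

#' @exportS3Method generics::glance
glance.ordination <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    k_retained = x$k_retained,
    method = x$method,
    stress = x$stress,
    leading_singular_value = if (length(x$singular_values)) x$singular_values[1]
                             else NA_real_
  )
}
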