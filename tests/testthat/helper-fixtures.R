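# Brute-force oracles and shared fixtures for the test suite.

# O(n^2) pair-enumeration tau-b oracle, independent of the package's
# merge-sort implementation.
tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      s <- dx * dy
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# dense eigendecomposition oracle for classical scaling of a similarity
# matrix (unit-diagonal tau); returns coordinates for the k leading
# |eigenvalue| axes
eigen_scaling_oracle <- function(tau, k) {
  n <- nrow(tau)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% tau %*% j
  b <- (b + t(b)) / 2
  ev <- eigen(b, symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)
  vals <- ev$values[ord][seq_len(k)]
  vecs <- ev$vectors[, ord, drop = FALSE][, seq_len(k), drop = FALSE]
  list(coords = vecs %*% diag(sqrt(abs(vals)), k, k),
       values = vals, b = b)
}

# random symmetric unit-diagonal association matrix wrapped as assoc_matrix
random_assoc <- function(n, species = NULL) {
  m <- matrix(runif(n * n, -0.9, 0.9), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ids <- sprintf("g%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  if (is.null(species)) species <- rep("mRNA", n)
  structure(list(gene_ids = ids, species = species, tau = m,
                 mode = "simple", covariate_name = NULL,
                 n_undefined_pairs = 0L),
            class = "assoc_matrix")
}

# assoc_matrix with prescribed off-diagonal taus (filled column-major into
# the upper triangle)
assoc_from_taus <- function(taus, n, species = NULL) {
  m <- diag(n)
  m[upper.tri(m)] <- taus
  m <- m + t(m) - diag(n)
  ids <- sprintf("g%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  if (is.null(species)) species <- rep("mRNA", n)
  structure(list(gene_ids = ids, species = species, tau = m,
                 mode = "simple", covariate_name = NULL,
                 n_undefined_pairs = 0L),
            class = "assoc_matrix")
}

small_config <- function(...) {
  args <- list(n_mirna = 20, n_mrna = 60, n_target_pairs = 24,
               n_seed_groups = 4)
  args[names(list(...))] <- list(...)
  do.call(study_config, args)
}

necrosis_of <- function(bundle) {
  bundle$samples$necrosis[bundle$samples$condition == "case"]
}

# all permutations of 1:n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# memoized full-size default bundle and its partial-correlation ordination,
# shared by the slower map-level tests
.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_study(study_config())
  }
  .fixture_cache$bundle
}

default_assoc <- function() {
  if (is.null(.fixture_cache$assoc)) {
    b <- default_bundle()
    .fixture_cache$assoc <- pairwise_matrix(
      b$case, covariate = necrosis_of(b), covariate_name = "necrosis")
  }
  .fixture_cache$assoc
}

default_ordination <- function(k = 50) {
  key <- paste0("ord", k)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- classical_scaling_svd(
      to_distance(default_assoc()), k = k)
  }
  .fixture_cache[[key]]
}
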