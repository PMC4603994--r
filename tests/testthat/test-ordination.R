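test_that("to_distance negates tau and preserves symmetry", {
  a <- withr::with_seed(61, random_assoc(6))
  d <- to_distance(a)
  expect_equal(d$d, -a$tau)
  expect_equal(d$d, t(d$d))
  expect_equal(unname(diag(d$d)), rep(-1, 6))
  # round-trip negation
  expect_equal(-d$d, a$tau)
  expect_equal(d$provenance$mode, "simple")
})

test_that("classical scaling reproduces the double-centered similarity", {
  withr::with_seed(31, {
    for (i in 1:5) {
      a <- random_assoc(20)
      d <- to_distance(a)
      ord <- classical_scaling_svd(d, k = 19)
      oracle <- eigen_scaling_oracle(a$tau, 19)
      expect_equal(unname(reconstruct_similarity(ord)), oracle$b,
                   tolerance = 1e-10)
      # axis-by-axis agreement with the eigen oracle up to sign
      for (j in 1:19) {
        agree <- min(sum(abs(ord$coordinates[, j] - oracle$coords[, j])),
                     sum(abs(ord$coordinates[, j] + oracle$coords[, j])))
        expect_lt(agree, 1e-6 * 20)
      }
    }
  })
})

test_that("duplicated association rows map to coincident points", {
  a <- withr::with_seed(62, random_assoc(8))
  a$tau[2, ] <- a$tau[1, ]
  a$tau[, 2] <- a$tau[, 1]
  a$tau[1, 2] <- a$tau[2, 1] <- a$tau[1, 1]
  ord <- classical_scaling_svd(to_distance(a), k = 3)
  expect_equal(ord$coordinates[1, ], ord$coordinates[2, ],
               tolerance = 1e-8)
})

test_that("three equally correlated genes form an equilateral triangle", {
  a <- assoc_from_taus(rep(0.4, 3), 3)
  ord <- classical_scaling_svd(to_distance(a), k = 2)
  dists <- as.vector(dist(ord$coordinates))
  expect_lt(max(dists) - min(dists), 1e-9)
})

test_that("classical scaling is equivariant under gene reordering", {
  withr::with_seed(63, {
    a <- random_assoc(12)
    perm <- sample(12)
  })
  ap <- a
  ap$tau <- a$tau[perm, perm]
  ap$gene_ids <- a$gene_ids[perm]
  ord <- classical_scaling_svd(to_distance(a), k = 4)
  ordp <- classical_scaling_svd(to_distance(ap), k = 4)
  expect_equal(ordp$coordinates[a$gene_ids, ], ord$coordinates,
               tolerance = 1e-8)
})

test_that("singular values are nonincreasing and k is validated", {
  a <- withr::with_seed(64, random_assoc(10))
  ord <- classical_scaling_svd(to_distance(a), k = 5)
  expect_true(all(diff(ord$singular_values) <= 1e-12))
  expect_true(all(ord$singular_values >= -1e-12))
  expect_error(classical_scaling_svd(to_distance(a), k = 10), "k must")
  expect_error(classical_scaling_svd(to_distance(a), k = 0), "k must")
  bad <- to_distance(a)
  bad$d[1, 2] <- bad$d[1, 2] + 0.5
  expect_error(classical_scaling_svd(bad, 2), "symmetric")
})

test_that("retained axes are mutually orthogonal", {
  a <- withr::with_seed(65, random_assoc(15))
  ord <- classical_scaling_svd(to_distance(a), k = 6)
  g <- crossprod(ord$coordinates)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("Sammon embedding of realizable distances reaches ~zero stress", {
  withr::with_seed(32, pts <- matrix(rnorm(20), 10, 2))
  dmat <- as.matrix(dist(pts))
  fake <- structure(
    list(gene_ids = sprintf("g%02d", 1:10), species = rep("mRNA", 10),
         d = dmat, provenance = list(mode = "simple", covariate_name = NULL)),
    class = "dist_matrix")
  s <- sammon_mapping(fake, k = 2)
  expect_lt(s$stress, 1e-4)
  kr <- kruskal_nmds(fake, k = 2)
  expect_lt(kr$stress, 0.01)
  expect_gte(kr$stress, 0)
})

test_that("nonmetric comparators agree with the SVD configuration", {
  b <- generate_study(small_config(rng_seed = 33))
  d <- to_distance(pairwise_matrix(b$case, covariate = necrosis_of(b)))
  o_svd <- classical_scaling_svd(d, k = 3)
  o_sam <- sammon_mapping(d, k = 3)
  o_kru <- kruskal_nmds(d, k = 3)
  expect_gt(configuration_agreement(o_svd, o_sam), 0.8)
  expect_gt(configuration_agreement(o_svd, o_kru), 0.8)
})

test_that("Procrustes correlation is invariant to rigid motion and scale", {
  a <- withr::with_seed(66, random_assoc(30))
  ord <- classical_scaling_svd(to_distance(a), k = 3)
  theta <- 0.7
  rot <- diag(3)
  rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                            -sin(theta), cos(theta)), 2)
  moved <- ord
  moved$coordinates <- 2.5 * ord$coordinates %*% rot
  moved$coordinates[, 3] <- -moved$coordinates[, 3]  # reflection
  expect_equal(configuration_agreement(ord, moved), 1, tolerance = 1e-8)
  expect_equal(configuration_agreement(ord, ord), 1, tolerance = 1e-10)
})

test_that("independent random configurations score near zero", {
  withr::with_seed(34, {
    mk <- function() {
      o <- classical_scaling_svd(to_distance(random_assoc(100)), k = 3)
      o
    }
    a <- mk(); b <- mk()
  })
  expect_lt(configuration_agreement(a, b), 0.5)
  c_ <- b
  c_$gene_ids[1] <- "other"
  rownames(c_$coordinates)[1] <- "other"
  expect_error(configuration_agreement(a, c_), "gene sets")
})
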