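test_that("dispersion ellipses recover isotropic spread at 1.6 SD", {
  withr::with_seed(41, pts <- matrix(rnorm(4000), 2000, 2))
  el <- dispersion_ellipse(pts, scale = 1.6)
  semi_axes <- 1.6 * sqrt(eigen(el$covariance)$values)
  expect_equal(unname(semi_axes), c(1.6, 1.6), tolerance = 0.1)
  expect_equal(unname(el$center), c(0, 0), tolerance = 0.1)
  expect_error(dispersion_ellipse(matrix(1:4, 2, 2)), "points")
  expect_error(dispersion_ellipse(matrix(1, 5, 2)), "degenerate")
})

test_that("dispersion ellipses are affinely equivariant", {
  withr::with_seed(42, pts <- matrix(rnorm(600), 300, 2))
  amat <- matrix(c(2, 0.5, -1, 1.5), 2)
  shift <- c(3, -4)
  el <- dispersion_ellipse(pts)
  elt <- dispersion_ellipse(sweep(pts %*% t(amat), 2, -shift))
  expect_equal(elt$center, el$center %*% t(amat) + shift |> as.vector(),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(elt$covariance, amat %*% el$covariance %*% t(amat),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("in_ellipse matches the Mahalanobis rule", {
  el <- dispersion_ellipse(matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), 4, 2))
  expect_true(in_ellipse(matrix(c(0, 0), 1), el))
  expect_false(in_ellipse(matrix(c(50, 50), 1), el))
})

test_that("density fields normalize and find the right modes", {
  withr::with_seed(43, pts <- matrix(rnorm(400, sd = 0.3), 200, 2))
  f <- kernel_density_field(pts, grid_size = 60)
  expect_equal(sum(f$z) * f$cell_area, 1, tolerance = 1e-6)
  peak <- which(f$z == max(f$z), arr.ind = TRUE)
  expect_equal(c(f$x[peak[1]], f$y[peak[2]]), c(0, 0), tolerance = 0.3)
  expect_error(kernel_density_field(pts[1, , drop = FALSE]), "2 points")
  expect_error(kernel_density_field(pts, bandwidth = 0), "bandwidth")
})

test_that("two separated clusters give two local density maxima", {
  withr::with_seed(44, {
    pts <- rbind(matrix(rnorm(200, -4, 0.5), 100, 2),
                 matrix(rnorm(200, 4, 0.5), 100, 2))
  })
  f <- kernel_density_field(pts, grid_size = 50)
  # local maxima along the diagonal profile
  prof <- diag(f$z)
  is_peak <- which(diff(sign(diff(prof))) == -2) + 1
  expect_gte(length(is_peak), 2)
})

test_that("complementarity contrasts overlapping and disjoint fields", {
  withr::with_seed(45, {
    a_pts <- matrix(rnorm(300, -3, 0.4), 150, 2)
    b_pts <- matrix(rnorm(300, 3, 0.4), 150, 2)
  })
  box <- kernel_density_field(rbind(a_pts, b_pts), grid_size = 40)
  fa <- ordimir:::density_on_grid(a_pts, box)
  fb <- ordimir:::density_on_grid(b_pts, box)
  expect_equal(complementarity_score(fa, fa), 1)
  expect_lt(complementarity_score(fa, fb), -0.3)
  flat <- fa
  flat$z <- matrix(1 / (length(fa$x)^2 * fa$cell_area),
                   length(fa$x), length(fa$y))
  expect_true(is.na(complementarity_score(flat, fb)))
  other_grid <- kernel_density_field(a_pts, grid_size = 40)
  expect_error(complementarity_score(other_grid, fb), "grids")
})

test_that("median shift classifies strictly beyond the threshold", {
  sp <- c(rep("miRNA", 3), rep("mRNA", 10))
  a <- withr::with_seed(81, random_assoc(13, species = sp))
  same <- median_correlation_shift(a, a)
  expect_true(all(same$delta == 0))
  expect_true(all(same$status == "stable"))

  shifted <- a
  shifted$tau[1, 4:13] <- shifted$tau[1, 4:13] - 0.3
  shifted$tau[4:13, 1] <- shifted$tau[1, 4:13]
  rep_ <- median_correlation_shift(shifted, a)
  expect_equal(rep_$status[rep_$mirna_id == "g01"], "decreased")

  # delta exactly at -threshold is not flagged (0.25 is binary-exact,
  # so the comparison is genuinely at the boundary)
  before <- a; after <- a
  before$tau[2, 4:13] <- 0.5;  before$tau[4:13, 2] <- 0.5
  after$tau[2, 4:13] <- 0.25;  after$tau[4:13, 2] <- 0.25
  rep2 <- median_correlation_shift(after, before, threshold = 0.25)
  expect_equal(rep2$status[rep2$mirna_id == "g02"], "stable")
})

test_that("median shift is antisymmetric in its two conditions", {
  sp <- c(rep("miRNA", 4), rep("mRNA", 8))
  withr::with_seed(82, {
    a <- random_assoc(12, species = sp)
    b <- random_assoc(12, species = sp)
  })
  b$tau <- (b$tau + t(b$tau)) / 2; diag(b$tau) <- 1
  ab <- median_correlation_shift(a, b)
  ba <- median_correlation_shift(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_setequal(ab$mirna_id[ab$status == "decreased"],
                  ba$mirna_id[ba$status == "increased"])
})

test_that("target-pair distances are invariant to rigid map motion", {
  b <- generate_study(small_config(rng_seed = 46))
  assoc <- pairwise_matrix(b$case, covariate = necrosis_of(b))
  ord <- classical_scaling_svd(to_distance(assoc), k = 3)
  rep_ <- target_pair_analysis(ord, assoc, b$targets, n_dims = 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  ord2 <- ord
  ord2$coordinates <- ord$coordinates %*% rot
  rep2 <- target_pair_analysis(ord2, assoc, b$targets, n_dims = 3)
  expect_equal(rep2$pairs$distance, rep_$pairs$distance, tolerance = 1e-8)
  expect_equal(rep2$mean_background, rep_$mean_background, tolerance = 1e-8)

  single <- target_pair_analysis(ord, assoc, b$targets[1, ], n_dims = 3)
  expect_equal(nrow(single$pairs), 1L)
  expect_error(target_pair_analysis(ord, assoc, b$targets[0, ]), "empty")
  expect_error(target_pair_analysis(ord, assoc, b$targets, n_dims = 9),
               "exceeds")
})

test_that("inhibitory-only couplings push targets beyond background", {
  b <- generate_study(small_config(feedforward_coupling = 0,
                                   inhibitory_coupling = 1.5,
                                   rng_seed = 47))
  assoc <- pairwise_matrix(b$case, covariate = necrosis_of(b))
  ord <- classical_scaling_svd(to_distance(assoc), k = 3)
  rep_ <- target_pair_analysis(ord, assoc, b$targets, n_dims = 3)
  expect_gt(rep_$mean_observed, rep_$mean_background)
})

test_that("mirSVR regression fits exact and guards thin designs", {
  b <- generate_study(small_config(rng_seed = 48))
  assoc <- pairwise_matrix(b$case, covariate = necrosis_of(b))
  ord <- classical_scaling_svd(to_distance(assoc), k = 5)
  targets <- b$targets
  d1 <- abs(ord$coordinates[targets$mirna_id, 1] -
              ord$coordinates[targets$mrna_id, 1])
  targets$mirsvr_score <- -0.1 - 0.8 * d1
  fit <- suppressWarnings(  # summary.lm warns on an essentially perfect fit
    mirsvr_distance_regression(ord, targets, n_dims = 1))
  expect_gt(fit$r_squared, 0.999)
  expect_lt(fit$p_value, 1e-10)

  expect_error(
    mirsvr_distance_regression(ord, targets[1:4, ], n_dims = 5),
    "pairs")
  const <- targets
  const$mirsvr_score <- -0.5
  flagged <- mirsvr_distance_regression(ord, const, n_dims = 1)
  expect_true(flagged$constant_response)
  expect_true(is.na(flagged$r_squared))
})

test_that("seed grouping normalizes case and T/U before matching", {
  tab <- tibble::tibble(
    mirna_id = c("a", "b", "c", "d", "e"),
    seed_sequence = c("gagguag", "GAGGTAG", "ACGUACG", "UUUUUUU", "ACGTACG"))
  gr <- seed_group_partition(tab)
  expect_equal(attr(gr, "n_groups"), 2L)
  expect_setequal(gr$mirna_id[gr$seed_sequence == "GAGGUAG"], c("a", "b"))
  expect_setequal(gr$mirna_id[gr$seed_sequence == "ACGUACG"], c("c", "e"))
  expect_equal(attr(gr, "n_singletons"), 1L)

  distinct <- tibble::tibble(mirna_id = c("x", "y"),
                             seed_sequence = c("AAAAAAA", "CCCCCCC"))
  expect_equal(nrow(seed_group_partition(distinct)), 0L)
  expect_error(seed_group_partition(distinct[0, ]), "empty")
})

test_that("planted blocks separate on the map", {
  b <- generate_study(small_config(rng_seed = 49))
  assoc <- pairwise_matrix(b$case, covariate = necrosis_of(b))
  ord <- classical_scaling_svd(to_distance(assoc), k = 3)
  sep <- block_separation(ord, b$truth$block_membership, n_dims = 3)
  expect_lt(sep$within_mean, sep$between_mean)
  expect_gt(sep$member_in_rate, sep$nonmember_in_rate)
})
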