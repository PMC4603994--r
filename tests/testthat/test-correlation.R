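test_that("kendall_tau_b reproduces hand-enumerated cases", {
  expect_equal(kendall_tau_b(1:6, (1:6)^2), 1)           # monotone
  expect_equal(kendall_tau_b(1:4, c(2, 1, 4, 3)), 1 / 3) # C=4, D=2
  # one tied pair per margin: C=4, D=0 -> 4 / sqrt(5 * 5)
  expect_equal(kendall_tau_b(c(1, 2, 2, 3), c(1, 2, 3, 3)), 0.8)
  expect_equal(kendall_tau_b(1:5, 5:1), -1)
  expect_true(is.na(kendall_tau_b(rep(1, 5), 1:5)))
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")
  expect_error(kendall_tau_b(1:2, 1:2), "at least 3")
})

test_that("merge-sort tau agrees with the pair-enumeration oracle and cor()", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(3:30, 1)
      x <- sample(0:8, n, replace = TRUE)  # heavy ties
      y <- sample(0:8, n, replace = TRUE)
      expected <- tau_oracle(x, y)
      got <- kendall_tau_b(x, y)
      if (is.na(expected)) expect_true(is.na(got)) else {
        expect_equal(got, expected, tolerance = 1e-14)
        expect_equal(got, suppressWarnings(cor(x, y, method = "kendall")),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("partial_kendall implements the first-order formula", {
  withr::with_seed(7, {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
    expected <- (kendall_tau_b(x, y) - kendall_tau_b(x, z) * kendall_tau_b(y, z)) /
      sqrt((1 - kendall_tau_b(x, z)^2) * (1 - kendall_tau_b(y, z)^2))
    expect_equal(partial_kendall(x, y, z), expected)
    # symmetry in x, y
    expect_equal(partial_kendall(x, y, z), partial_kendall(y, x, z))
  })
})

test_that("partial_kendall handles degenerate covariates", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  # covariate identical to x: collinear, undefined
  expect_true(is.na(partial_kendall(x, y, x)))
  # constant input propagates undefined
  expect_true(is.na(partial_kendall(x, y, rep(1, 8))))
})

test_that("a rank-orthogonal covariate leaves tau unchanged", {
  # z chosen so that tau(x, z) = tau(y, z) = 0 exactly
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  # search the permutations of 1:4 for a z with both cross-taus exactly zero
  found <- NULL
  for (p in combinat_perms(4)) {
    if (abs(kendall_tau_b(x, p)) < 1e-12 &&
        abs(kendall_tau_b(y, p)) < 1e-12) { found <- p; break }
  }
  expect_false(is.null(found))
  expect_equal(partial_kendall(x, y, found), kendall_tau_b(x, y))
})

test_that("pairwise_matrix is symmetric with unit diagonal", {
  b <- generate_study(small_config(rng_seed = 11))
  a <- pairwise_matrix(b$case)
  expect_equal(a$tau, t(a$tau))
  expect_equal(unname(diag(a$tau)), rep(1, 80))
  expect_true(all(abs(a$tau[upper.tri(a$tau)]) <= 1))
  expect_equal(a$mode, "simple")

  ap <- pairwise_matrix(b$case, covariate = necrosis_of(b),
                        covariate_name = "necrosis")
  expect_equal(ap$mode, "partial")
  expect_equal(ap$covariate_name, "necrosis")
  # the covariate genuinely changes the matrix on confounded data
  expect_gt(max(abs(ap$tau - a$tau)), 0.1)
})

test_that("identical gene rows correlate perfectly", {
  v <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  v[2, ] <- v[1, ]
  a <- pairwise_matrix(expr_matrix(v, "mRNA"))
  expect_equal(a$tau["g1", "g2"], 1)
})

test_that("constant genes and covariates are rejected, not zero-filled", {
  v <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  v[2, ] <- 5
  m <- expr_matrix(v, "mRNA")
  expect_error(pairwise_matrix(m), "g2")
  dropped <- pairwise_matrix(m, drop_constant = TRUE)
  expect_equal(dropped$gene_ids, c("g1", "g3"))
  expect_error(
    pairwise_matrix(expr_matrix(v[-2, , drop = FALSE], "mRNA"),
                    covariate = rep(2, 10)),
    "constant covariate")
})

test_that("distribution_profile counts every pair and flags mixtures", {
  a3 <- withr::with_seed(67, random_assoc(3))
  p3 <- distribution_profile(a3)
  expect_equal(sum(p3$counts), 3L)

  withr::with_seed(1, {
    unimodal <- assoc_from_taus(pmax(pmin(rnorm(4950, 0, 0.1), 1), -1), 100)
    mixture <- assoc_from_taus(
      pmax(pmin(c(rnorm(2475, -0.8, 0.05), rnorm(2475, 0.8, 0.05)), 1), -1),
      100)
  })
  expect_lte(distribution_profile(unimodal)$bimodality_coefficient, 5 / 9)
  expect_false(distribution_profile(unimodal)$bimodal)
  expect_gt(distribution_profile(mixture)$bimodality_coefficient, 5 / 9)
  expect_true(distribution_profile(mixture)$bimodal)
  # density integrates to ~1
  prof <- distribution_profile(mixture)
  dx <- diff(prof$density$tau[1:2])
  expect_equal(sum(prof$density$density) * dx, 1, tolerance = 0.02)
})

test_that("the uniform distribution sits at the 5/9 bimodality benchmark", {
  withr::with_seed(2, u <- runif(2e5, -1, 1))
  expect_equal(bimodality_coefficient(u), 5 / 9, tolerance = 0.01)
})
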