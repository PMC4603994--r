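#' Dispersion ellipse of a labeled point cloud
#'
#' Center and sample covariance of the points, drawn at `scale` standard
#' deviations (default 1.6, the convention used for functional-class
#' ellipses on co-expression maps). This is the covariance-ellipse ("sd")
#' convention, not a chi-square quantile.
#'
#' @param points n x k coordinate matrix with `n >= k + 1`.
#' @param scale SD multiplier.
#' @param label optional class label.
#' @return an object of class `ellipse_spec` with `center`, `covariance`,
#'   `scale`, `label`.
#' @export
dispersion_ellipse <- function(points, scale = 1.6, label = NULL) {
  points <- as.matrix(points)
  n <- nrow(points); k <- ncol(points)
  if (n < k + 1) abort(sprintf("need at least k + 1 = %d points", k + 1))
  if (all(apply(points, 2, function(c) all(c == c[1])))) {
    abort("all points identical: degenerate ellipse")
  }
  structure(
    list(center = colMeans(points), covariance = stats::cov(points),
         scale = scale, label = label),
    class = "ellipse_spec"
  )
}

#' Test whether points fall inside a dispersion ellipse
#'
#' A point is inside when its Mahalanobis distance from the ellipse center is
#' at most `scale`.
#'
#' @param points n x k coordinate matrix.
#' @param ellipse an [dispersion_ellipse()] spec.
#' @return logical vector of length n.
#' @export
in_ellipse <- function(points, ellipse) {
  points <- as.matrix(points)
  md2 <- stats::mahalanobis(points, ellipse$center, ellipse$covariance)
  md2 <= ellipse$scale^2
}

#' Gaussian kernel density field over an ordination plane
#'
#' Two-dimensional kernel density estimate on a regular grid covering the
#' points' bounding box with a 10% margin, normalized to integrate to 1 over
#' the grid.
#'
#' @param points n x 2 coordinate matrix.
#' @param grid_size grid points per axis.
#' @param bandwidth scalar or length-2 bandwidth; `NULL` for the normal
#'   reference rule.
#' @return an object of class `density_field` with `x`, `y`, `z`
#'   (grid_size x grid_size), `bandwidth`, `cell_area`.
#' @export
kernel_density_field <- function(points, grid_size = 100, bandwidth = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2) abort("need at least 2 points")
  if (ncol(points) != 2) abort("density fields are two-dimensional")
  if (!is.null(bandwidth) && any(bandwidth <= 0)) abort("zero bandwidth")
  rng_x <- range(points[, 1]); rng_y <- range(points[, 2])
  mx <- 0.1 * max(diff(rng_x), 1e-8); my <- 0.1 * max(diff(rng_y), 1e-8)
  lims <- c(rng_x[1] - mx, rng_x[2] + mx, rng_y[1] - my, rng_y[2] + my)
  h <- if (is.null(bandwidth)) {
    c(MASS::bandwidth.nrd(points[, 1]), MASS::bandwidth.nrd(points[, 2]))
  } else rep_len(bandwidth, 2)
  h[h <= 0] <- 1e-3
  kd <- MASS::kde2d(points[, 1], points[, 2], h = h, n = grid_size,
                    lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * cell)
  structure(
    list(x = kd$x, y = kd$y, z = z, bandwidth = h, cell_area = cell),
    class = "density_field"
  )
}

#' Complementarity of two density fields
#'
#' Spearman correlation of the two density surfaces across grid cells;
#' negative values mean the two species occupy complementary regions of the
#' map (the miRNA-vs-mRNA density contrast). The fields must share a grid.
#'
#' @param field_a,field_b `density_field` objects on identical grids.
#' @return scalar in `[-1, 1]`, `NA` when a field has no rank variation.
#' @export
complementarity_score <- function(field_a, field_b) {
  if (!isTRUE(all.equal(field_a$x, field_b$x)) ||
      !isTRUE(all.equal(field_a$y, field_b$y))) {
    abort("density fields are on different grids")
  }
  za <- as.vector(field_a$z); zb <- as.vector(field_b$z)
  if (var(za) == 0 || var(zb) == 0) return(NA_real_)
  cor(za, zb, method = "spearman")
}

#' Shift in per-miRNA median correlation with mRNAs between two conditions
#'
#' For each miRNA, the median Kendall tau against all mRNAs is computed in
#' each condition; miRNAs whose delta (`condition A - condition B`) falls
#' strictly below `-threshold` are reported as decreased, strictly above
#' `+threshold` as increased (default threshold 0.15 tau).
#'
#' @param assoc_a,assoc_b `assoc_matrix` objects over the same genes with
#'   species tags.
#' @param threshold strict classification threshold on the delta.
#' @return a tibble (class `median_shift_report`) with per-miRNA medians,
#'   `delta` and `status` in `decreased`/`increased`/`stable`.
#' @export
median_correlation_shift <- function(assoc_a, assoc_b, threshold = 0.15) {
  if (!setequal(assoc_a$gene_ids, assoc_b$gene_ids)) {
    abort("the two association matrices cover different gene sets")
  }
  mirnas <- assoc_a$gene_ids[assoc_a$species == "miRNA"]
  mrnas <- assoc_a$gene_ids[assoc_a$species == "mRNA"]
  if (length(mrnas) == 0) abort("no mRNAs present")
  if (length(mirnas) == 0) abort("no miRNAs present")
  med <- function(assoc) {
    apply(assoc$tau[mirnas, mrnas, drop = FALSE], 1, median)
  }
  ma <- med(assoc_a); mb <- med(assoc_b)
  delta <- ma - mb
  out <- tibble::tibble(
    mirna_id = mirnas,
    median_a = unname(ma),
    median_b = unname(mb[mirnas]),
    delta = unname(delta),
    status = dplyr::case_when(
      delta < -threshold ~ "decreased",
      delta > threshold ~ "increased",
      TRUE ~ "stable"
    )
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("median_shift_report", class(out))
  out
}

pair_distances <- function(coords, id_a, id_b, n_dims) {
  da <- coords[id_a, seq_len(n_dims), drop = FALSE]
  db <- coords[id_b, seq_len(n_dims), drop = FALSE]
  sqrt(rowSums((da - db)^2))
}

#' Map-distance analysis of miRNA-mRNA target pairs with a sign-flip control
#'
#' Computes the Euclidean map distance (first `n_dims` retained dimensions)
#' of every declared target pair, the background distribution over all
#' miRNA-mRNA id pairs, and a sign-flip control: the miRNA-vs-mRNA blocks of
#' the association matrix are negated (symmetrically), the ordination is
#' recomputed with identical settings, and the mean target-pair distance is
#' measured again. When inhibitory and feed-forward couplings balance, the
#' sign flip leaves the mean target distance essentially unchanged.
#'
#' @param ord a classical-SVD `ordination` of `assoc`.
#' @param assoc the `assoc_matrix` the ordination was built from.
#' @param targets tibble with `mirna_id`, `mrna_id` columns.
#' @param n_dims map dimensionality for the distances (<= `k_retained`).
#' @return an object of class `target_distance_report`.
#' @export
target_pair_analysis <- function(ord, assoc, targets, n_dims = 3) {
  if (nrow(targets) == 0) abort("empty target table")
  if (n_dims > ord$k_retained) abort("n_dims exceeds retained dimensions")
  missing <- setdiff(c(targets$mirna_id, targets$mrna_id), ord$gene_ids)
  if (length(missing) > 0) {
    abort(paste0("target genes absent from the ordination: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  obs <- pair_distances(ord$coordinates, targets$mirna_id, targets$mrna_id,
                        n_dims)
  mir <- ord$gene_ids[ord$species == "miRNA"]
  mr <- ord$gene_ids[ord$species == "mRNA"]
  grid <- expand.grid(mirna_id = mir, mrna_id = mr,
                      stringsAsFactors = FALSE)
  bg <- pair_distances(ord$coordinates, grid$mirna_id, grid$mrna_id, n_dims)

  # sign-flip arm: negate the cross-species blocks and re-run the MDS
  flipped <- assoc
  is_mir <- assoc$species == "miRNA"
  flipped$tau[is_mir, !is_mir] <- -flipped$tau[is_mir, !is_mir]
  flipped$tau[!is_mir, is_mir] <- -flipped$tau[!is_mir, is_mir]
  ord_flip <- classical_scaling_svd(to_distance(flipped), k = ord$k_retained)
  flip <- pair_distances(ord_flip$coordinates, targets$mirna_id,
                         targets$mrna_id, n_dims)

  structure(
    list(
      pairs = tibble::tibble(
        mirna_id = targets$mirna_id, mrna_id = targets$mrna_id,
        distance = obs, signflip_distance = flip
      ),
      mean_observed = mean(obs),
      mean_background = mean(bg),
      sd_background = sd(bg),
      mean_signflip = mean(flip),
      n_dims = n_dims
    ),
    class = "target_distance_report"
  )
}

#' @export
print.target_distance_report <- function(x, ...) {
  cat(sprintf(
    "<target_distance_report> %d pairs in %d dims: observed %.3f, background %.3f (sd %.3f), sign-flip %.3f\n",
    nrow(x$pairs), x$n_dims, x$mean_observed, x$mean_background,
    x$sd_background, x$mean_signflip))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.target_distance_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs), n_dims = x$n_dims,
    mean_observed = x$mean_observed,
    mean_background = x$mean_background,
    sd_background = x$sd_background,
    mean_signflip = x$mean_signflip
  )
}

#' Multiple regression of mirSVR scores on per-dimension map distances
#'
#' Response: the mirSVR predicted-repression score of each target pair.
#' Predictors: the absolute per-dimension coordinate differences
#' `|x_d(miRNA) - x_d(mRNA)|` for the first `n_dims` retained dimensions
#' (default 50). Ordinary least squares; the overall F-test p-value and
#' multiple R-squared quantify whether predicted repression strength leaves a
#' trace in the map geometry.
#'
#' @param ord an `ordination` with `k_retained >= n_dims`.
#' @param targets tibble with `mirna_id`, `mrna_id`, `mirsvr_score`.
#' @param n_dims number of per-dimension distance predictors.
#' @return a list of class `mirsvr_regression` with `r_squared`, `p_value`,
#'   `n_pairs`, `n_dims` and the fitted `lm` object.
#' @export
mirsvr_distance_regression <- function(ord, targets, n_dims = 50) {
  if (n_dims > ord$k_retained) abort("n_dims exceeds retained dimensions")
  if (nrow(targets) <= n_dims + 1) {
    abort(sprintf("need more than n_dims + 1 = %d pairs, got %d",
                  n_dims + 1, nrow(targets)))
  }
  missing <- setdiff(c(targets$mirna_id, targets$mrna_id), ord$gene_ids)
  if (length(missing) > 0) {
    abort(paste0("target genes absent from the ordination: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  da <- ord$coordinates[targets$mirna_id, seq_len(n_dims), drop = FALSE]
  db <- ord$coordinates[targets$mrna_id, seq_len(n_dims), drop = FALSE]
  preds <- abs(da - db)
  colnames(preds) <- paste0("dist_dim", seq_len(n_dims))
  y <- targets$mirsvr_score
  if (var(y) == 0) {
    out <- list(r_squared = NA_real_, p_value = NA_real_,
                n_pairs = nrow(targets), n_dims = n_dims, fit = NULL,
                constant_response = TRUE)
    class(out) <- "mirsvr_regression"
    return(out)
  }
  df <- data.frame(mirsvr_score = y, preds)
  fit <- lm(mirsvr_score ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(
    list(r_squared = sm$r.squared, p_value = p, n_pairs = nrow(targets),
         n_dims = n_dims, fit = fit, constant_response = FALSE),
    class = "mirsvr_regression"
  )
}

#' @export
print.mirsvr_regression <- function(x, ...) {
  cat(sprintf(
    "<mirsvr_regression> %d pairs, %d dims: R^2 = %.3f, overall p = %.4f\n",
    x$n_pairs, x$n_dims, x$r_squared, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mirsvr_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value,
                 n_pairs = x$n_pairs, n_dims = x$n_dims)
}

#' Group miRNAs by identical seed sequence
#'
#' Seeds are normalized (uppercase, T to U) before exact matching; groups of
#' size >= 2 are returned, singletons only counted in the attributes.
#'
#' @param seeds tibble with `mirna_id`, `seed_sequence`.
#' @return a tibble (class `seed_groups`) with `group_id`, `seed_sequence`,
#'   `mirna_id`; attribute `n_singletons` counts unshared seeds.
#' @export
seed_group_partition <- function(seeds) {
  if (nrow(seeds) == 0) abort("empty seed table")
  norm <- gsub("T", "U", toupper(seeds$seed_sequence), fixed = TRUE)
  tab <- tibble::tibble(mirna_id = seeds$mirna_id, seed_sequence = norm)
  grouped <- tab |>
    dplyr::add_count(.data$seed_sequence, name = "group_size") |>
    dplyr::filter(.data$group_size >= 2) |>
    dplyr::arrange(.data$seed_sequence, .data$mirna_id) |>
    dplyr::mutate(group_id = dplyr::dense_rank(.data$seed_sequence)) |>
    dplyr::select("group_id", "seed_sequence", "mirna_id")
  attr(grouped, "n_singletons") <-
    sum(table(norm) == 1)
  attr(grouped, "n_groups") <- dplyr::n_distinct(grouped$group_id)
  class(grouped) <- c("seed_groups", class(grouped))
  grouped
}

#' Planted-block separation diagnostics on a map
#'
#' For each annotated class, compares within-class to between-class mean
#' pairwise map distances and the rate at which members versus non-members
#' fall inside the class's dispersion ellipse.
#'
#' @param ord an `ordination`.
#' @param classes named character vector (gene id -> class label, `NA` for
#'   unannotated genes).
#' @param n_dims map dimensionality used for distances and ellipses.
#' @param scale ellipse SD multiplier.
#' @return a list with `within_mean`, `between_mean`, `member_in_rate`,
#'   `nonmember_in_rate` and the per-class tibble `per_class`.
#' @export
block_separation <- function(ord, classes, n_dims = 3, scale = 1.6) {
  coords <- ord$coordinates[, seq_len(n_dims), drop = FALSE]
  cls <- classes[ord$gene_ids]
  keep <- !is.na(cls)
  coords <- coords[keep, , drop = FALSE]
  cls <- cls[keep]
  labs <- unique(cls)
  dmat <- as.matrix(stats::dist(coords))
  same <- outer(cls, cls, "==")
  ut <- upper.tri(dmat)
  within_mean <- mean(dmat[ut & same])
  between_mean <- mean(dmat[ut & !same])
  per_class <- purrr::map_dfr(labs, function(lb) {
    pts <- coords[cls == lb, , drop = FALSE]
    el <- dispersion_ellipse(pts, scale = scale, label = lb)
    tibble::tibble(
      class = lb,
      n = nrow(pts),
      member_in_rate = mean(in_ellipse(pts, el)),
      nonmember_in_rate = mean(in_ellipse(coords[cls != lb, , drop = FALSE], el))
    )
  })
  list(
    within_mean = within_mean,
    between_mean = between_mean,
    member_in_rate = stats::weighted.mean(per_class$member_in_rate,
                                          per_class$n),
    nonmember_in_rate = stats::weighted.mean(per_class$nonmember_in_rate,
                                             per_class$n),
    per_class = per_class
  )
}
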