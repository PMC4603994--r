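#' Full-run configuration
#'
#' Exactly one of `simulation` (a [study_config()]) or `input_dir` (a
#' directory of TSV tables as written by [write_study_bundle()]) must be
#' given. Stage parameters default to the analysis' canonical values:
#' FDR 1% at 80% confidence, fold-change threshold 5, covariate screen 0.9,
#' ellipse scale 1.6, median-shift threshold 0.15, 50 regression dimensions,
#' mirSVR cutoff -0.1.
#'
#' @param simulation a [study_config()] or `NULL`.
#' @param input_dir directory of input TSVs or `NULL`.
#' @param fdr_target,confidence,n_permutations,fc_threshold DE-stage
#'   parameters.
#' @param run_selection whether to run the DE selection stage (the synthetic
#'   generator already emits differentially expressed panels, so the stage is
#'   optional on simulated input).
#' @param screen_threshold covariate screen cutoff on `|R|`.
#' @param mds_method `"svd"`, `"sammon"` or `"kruskal"`.
#' @param k_map,k_regression retained dimensions for maps and for the mirSVR
#'   regression.
#' @param shift_threshold median-correlation shift threshold.
#' @param ellipse_scale dispersion-ellipse SD multiplier.
#' @param mirsvr_cutoff keep target pairs with score <= this value.
#' @param rng_seed integer seed for all stochastic stages.
#' @param out_dir output directory, or `NULL` to keep results in memory only.
#' @return a list of class `run_config`.
#' @export
run_config <- function(simulation = study_config(), input_dir = NULL,
                       fdr_target = 0.01, confidence = 0.8,
                       n_permutations = 1000, fc_threshold = 5,
                       run_selection = FALSE,
                       screen_threshold = 0.9,
                       mds_method = c("svd", "sammon", "kruskal"),
                       k_map = 3, k_regression = 50,
                       shift_threshold = 0.15, ellipse_scale = 1.6,
                       mirsvr_cutoff = -0.1,
                       rng_seed = 1L, out_dir = NULL) {
  if (!is.null(simulation) && !is.null(input_dir)) {
    abort("provide either a simulation config or an input directory, not both")
  }
  if (is.null(simulation) && is.null(input_dir)) {
    abort("one of 'simulation' or 'input_dir' is required")
  }
  cfg <- list(
    simulation = simulation, input_dir = input_dir,
    fdr_target = fdr_target, confidence = confidence,
    n_permutations = n_permutations, fc_threshold = fc_threshold,
    run_selection = run_selection,
    screen_threshold = screen_threshold,
    mds_method = match.arg(mds_method),
    k_map = k_map, k_regression = k_regression,
    shift_threshold = shift_threshold, ellipse_scale = ellipse_scale,
    mirsvr_cutoff = mirsvr_cutoff,
    rng_seed = as.integer(rng_seed), out_dir = out_dir
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [run_config()] arguments; a `simulation:` mapping is
#' passed to [study_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(study_config, y$simulation)
  }
  do.call(run_config, y)
}

stage_msg <- function(...) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest) -> optional differential-expression
#' selection -> simple and partial correlation matrices -> covariate
#' diagnostics -> distance transform and ordination -> thematic map
#' statistics. Returns every stage result plus a manifest; when
#' `config$out_dir` is set, stage outputs are written as TSVs and the
#' manifest records a content hash per file.
#'
#' @param config a [run_config()].
#' @return a list of class `study_run`.
#' @export
run_study_pipeline <- function(config = run_config()) {
  t0 <- Sys.time()
  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(config$simulation)) {
      stage_msg("stage simulate: generating synthetic study")
      bundle <- generate_study(config$simulation)
    } else {
      stage_msg("stage ingest: reading %s", config$input_dir)
      bundle <- read_study_tables(config$input_dir)
    }

    case <- bundle$case; control <- bundle$control
    samples <- bundle$samples
    necrosis <- samples$necrosis[match(expr_samples(case),
                                       samples$sample_id)]

    selection <- NULL
    if (isTRUE(config$run_selection)) {
      stage <- "select"
      stage_msg("stage select: permutation F-test at FDR %g%%, %g%% confidence",
                100 * config$fdr_target, 100 * config$confidence)
      merged_all <- expr_matrix(
        cbind(expr_values(case), expr_values(control)),
        case$species)
      labels <- c(rep("case", length(expr_samples(case))),
                  rep("control", length(expr_samples(control))))
      selection <- permutation_f_select(
        merged_all, labels, fdr_target = config$fdr_target,
        confidence = config$confidence,
        n_permutations = config$n_permutations,
        rng_seed = config$rng_seed)
      fc <- vapply(seq_along(selection$f_statistic), function(i) {
        g <- names(selection$f_statistic)[i]
        signed_fold_change(expr_values(case)[g, ], expr_values(control)[g, ])
      }, numeric(1))
      names(fc) <- names(selection$f_statistic)
      mrna_sel <- selection$selected_ids[
        expr_species(case)[selection$selected_ids] == "mRNA"]
      mrna_kept <- fold_change_filter(mrna_sel, fc, config$fc_threshold)
      keep <- c(selection$selected_ids[
        expr_species(case)[selection$selected_ids] == "miRNA"], mrna_kept)
      if (length(keep) >= 8) {
        case <- filter_rows(case, keep)
        control <- filter_rows(control, keep)
      } else {
        warn("selection kept fewer than 8 genes; downstream stages use the full panel")
      }
    }

    stage <- "correlate"
    stage_msg("stage correlate: %d genes, %d + %d samples",
              nrow(case), length(expr_samples(case)),
              length(expr_samples(control)))
    assoc_case_simple <- pairwise_matrix(case)
    assoc_case <- pairwise_matrix(case, covariate = necrosis,
                                  covariate_name = "necrosis")
    assoc_control <- pairwise_matrix(control)

    profiles <- list(
      case_simple = distribution_profile(assoc_case_simple),
      case_partial = distribution_profile(assoc_case),
      control = distribution_profile(assoc_control)
    )

    stage <- "covariate"
    stage_msg("stage covariate: screen at |R| > %g", config$screen_threshold)
    screen <- covariate_screen(case, necrosis,
                               threshold = config$screen_threshold)
    correction <- zero_covariate_expression(case, necrosis)
    control_means <- rowMeans(expr_values(control))
    raw_agreement <- cross_condition_agreement(
      control_means, stats::setNames(rowMeans(expr_values(case)),
                                     expr_genes(case)))
    corrected_agreement <- cross_condition_agreement(
      control_means, stats::setNames(correction$intercept,
                                     correction$gene_id))

    stage <- "ordinate"
    k <- min(max(config$k_map, config$k_regression),
             length(assoc_case$gene_ids) - 1)
    stage_msg("stage ordinate: method=%s, k=%d", config$mds_method, k)
    dist_case <- to_distance(assoc_case)
    ord <- switch(config$mds_method,
      svd = classical_scaling_svd(dist_case, k = k),
      sammon = sammon_mapping(dist_case, k = k, rng_seed = config$rng_seed),
      kruskal = kruskal_nmds(dist_case, k = k, rng_seed = config$rng_seed))

    stage <- "maps"
    stage_msg("stage maps: thematic statistics")
    shift <- median_correlation_shift(assoc_case, assoc_control,
                                      threshold = config$shift_threshold)
    targets <- dplyr::filter(bundle$targets,
                             .data$mirsvr_score <= config$mirsvr_cutoff,
                             .data$conserved,
                             .data$mirna_id %in% expr_genes(case),
                             .data$mrna_id %in% expr_genes(case))
    target_report <- NULL
    if (nrow(targets) > 0 && config$mds_method == "svd") {
      target_report <- target_pair_analysis(ord, assoc_case, targets,
                                            n_dims = config$k_map)
    }
    regression <- NULL
    if (nrow(targets) > config$k_regression + 1 &&
        ord$k_retained >= config$k_regression) {
      regression <- mirsvr_distance_regression(ord, targets,
                                               n_dims = config$k_regression)
    }
    seed_groups <- if (!is.null(bundle$seeds) && nrow(bundle$seeds) > 0) {
      seed_group_partition(bundle$seeds)
    }
    is_mir <- ord$species == "miRNA"
    dens_mirna <- kernel_density_field(ord$coordinates[is_mir, 1:2])
    dens_mrna <- kernel_density_field(
      ord$coordinates[!is_mir, 1:2], bandwidth = dens_mirna$bandwidth)
    # shared grid for complementarity: recompute both on the union box
    all_pts <- ord$coordinates[, 1:2]
    grid_box <- kernel_density_field(all_pts)
    dens_mirna <- density_on_grid(ord$coordinates[is_mir, 1:2], grid_box)
    dens_mrna <- density_on_grid(ord$coordinates[!is_mir, 1:2], grid_box)
    complementarity <- complementarity_score(dens_mirna, dens_mrna)

    list(bundle = bundle, selection = selection,
         assoc_case_simple = assoc_case_simple,
         assoc_case = assoc_case, assoc_control = assoc_control,
         profiles = profiles, screen = screen, correction = correction,
         raw_agreement = raw_agreement,
         corrected_agreement = corrected_agreement,
         ordination = ord, shift = shift, target_report = target_report,
         regression = regression, seed_groups = seed_groups,
         density = list(mirna = dens_mirna, mrna = dens_mrna),
         complementarity = complementarity)
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- write_run_outputs(res, config)
  }
  res$manifest <- manifest
  res$config <- config
  res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(res) <- "study_run"
  res
}

# evaluate a KDE for points on the grid of an existing field
density_on_grid <- function(points, field) {
  n <- length(field$x)
  h <- field$bandwidth
  kd <- MASS::kde2d(points[, 1], points[, 2], h = h, n = n,
                    lims = c(range(field$x), range(field$y)))
  z <- kd$z / (sum(kd$z) * field$cell_area)
  structure(list(x = kd$x, y = kd$y, z = z, bandwidth = h,
                 cell_area = field$cell_area),
            class = "density_field")
}

write_run_outputs <- function(res, config) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_assoc <- function(assoc, path) {
    df <- data.frame(gene_id = assoc$gene_ids,
                     signif(assoc$tau, 8), check.names = FALSE)
    colnames(df) <- c("gene_id", assoc$gene_ids)
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_assoc(res$assoc_case, p("assoc_case_partial.tsv"))
  write_assoc(res$assoc_control, p("assoc_control_simple.tsv"))
  readr::write_tsv(tidy(res$ordination), p("coordinates.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$shift, p("median_shift.tsv"), progress = FALSE)
  readr::write_tsv(res$screen, p("covariate_screen.tsv"), progress = FALSE)
  readr::write_tsv(res$correction, p("intercept_correction.tsv"),
                   progress = FALSE)
  if (!is.null(res$target_report)) {
    readr::write_tsv(res$target_report$pairs, p("target_distances.tsv"),
                     progress = FALSE)
  }
  if (!is.null(res$seed_groups)) {
    readr::write_tsv(res$seed_groups, p("seed_groups.tsv"), progress = FALSE)
  }
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tibble::tibble(
    file = basename(files),
    sha1 = unname(vapply(files,
                         function(f) digest::digest(file = f, algo = "sha1"),
                         character(1))),
    rng_seed = config$rng_seed
  )
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf(
    paste0("<study_run> %d genes; bimodality (case simple/partial/control): ",
           "%.3f / %.3f / %.3f; raw vs corrected agreement: %.3f -> %.3f\n"),
    length(x$assoc_case$gene_ids),
    x$profiles$case_simple$bimodality_coefficient,
    x$profiles$case_partial$bimodality_coefficient,
    x$profiles$control$bimodality_coefficient,
    x$raw_agreement, x$corrected_agreement))
  invisible(x)
}
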