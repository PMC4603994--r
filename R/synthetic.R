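#' Configuration of a synthetic confounded case/control study
#'
#' Defaults emulate the motivating study design: 109 differentially expressed
#' miRNAs and 531 mRNAs profiled in 13 diseased (acute liver failure-like)
#' and 17 control livers, with an ordinal necrosis grade per diseased sample
#' acting as a confounding covariate that pushes hepatocyte genes down and
#' infiltrate genes up, nine functional co-expression blocks among the mRNAs,
#' and miRNA-mRNA couplings of both inhibitory (negative) and feed-forward
#' (positive) sign.
#'
#' @param n_mirna,n_mrna gene counts per species.
#' @param n_case_samples,n_control_samples sample counts.
#' @param n_functional_blocks number of mRNA co-expression blocks.
#' @param frac_hepatocyte_genes fraction of genes with hepatocyte
#'   (necrosis-down) direction; an equal fraction is infiltrate
#'   (necrosis-up) and the remainder neutral. Must satisfy
#'   `2 * frac_hepatocyte_genes <= 1`.
#' @param necrosis_grades ordinal grades recycled over the case samples.
#' @param covariate_effect log2 shift per necrosis grade unit.
#' @param block_effect_sd standard deviation of the per-sample block factor.
#' @param inhibitory_coupling,feedforward_coupling strengths of the two
#'   coupling mechanisms (log2 units per latent factor unit).
#' @param noise_sd residual Gaussian noise standard deviation (log2 units).
#' @param n_target_pairs number of coupled miRNA-mRNA pairs (all declared in
#'   the target table).
#' @param n_seed_groups number of miRNA pairs sharing an identical 7-base
#'   seed sequence.
#' @param rng_seed integer seed; the bundle is a pure function of the config.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n_mirna = 109, n_mrna = 531,
                         n_case_samples = 13, n_control_samples = 17,
                         n_functional_blocks = 9,
                         frac_hepatocyte_genes = 0.5,
                         necrosis_grades = 1:4,
                         covariate_effect = 1.0,
                         block_effect_sd = 0.5,
                         inhibitory_coupling = 1.0,
                         feedforward_coupling = 1.0,
                         noise_sd = 0.5,
                         n_target_pairs = 200,
                         n_seed_groups = 8,
                         rng_seed = 1L) {
  cfg <- list(
    n_mirna = n_mirna, n_mrna = n_mrna,
    n_case_samples = n_case_samples, n_control_samples = n_control_samples,
    n_functional_blocks = n_functional_blocks,
    frac_hepatocyte_genes = frac_hepatocyte_genes,
    necrosis_grades = necrosis_grades,
    covariate_effect = covariate_effect,
    block_effect_sd = block_effect_sd,
    inhibitory_coupling = inhibitory_coupling,
    feedforward_coupling = feedforward_coupling,
    noise_sd = noise_sd,
    n_target_pairs = n_target_pairs,
    n_seed_groups = n_seed_groups,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      abort(sprintf("invalid config: '%s' must be a count >= 1", field))
    }
  }
  for (f in c("n_mirna", "n_mrna", "n_case_samples", "n_control_samples",
              "n_functional_blocks")) chk_count(f)
  if (cfg$noise_sd <= 0) abort("invalid config: 'noise_sd' must be > 0")
  for (f in c("covariate_effect", "block_effect_sd",
              "inhibitory_coupling", "feedforward_coupling")) {
    if (cfg[[f]] < 0) abort(sprintf("invalid config: '%s' must be >= 0", f))
  }
  if (cfg$frac_hepatocyte_genes < 0 || cfg$frac_hepatocyte_genes > 1 ||
      2 * cfg$frac_hepatocyte_genes > 1 + 1e-12) {
    abort("invalid config: 'frac_hepatocyte_genes' must lie in [0, 0.5]")
  }
  if (cfg$n_target_pairs < 0 ||
      cfg$n_target_pairs > cfg$n_mirna * cfg$n_mrna) {
    abort("invalid config: 'n_target_pairs' exceeds n_mirna * n_mrna")
  }
  if (cfg$n_seed_groups < 0 || 2 * cfg$n_seed_groups > cfg$n_mirna) {
    abort("invalid config: 'n_seed_groups' needs 2 miRNAs per group")
  }
  if (length(cfg$necrosis_grades) < 1) {
    abort("invalid config: 'necrosis_grades' must be nonempty")
  }
  cfg
}

# The nine functional classes used for block labels.
functional_classes <- c(
  "CYP450", "transcription_factors", "complement", "proliferation",
  "HLA_class_II", "monocytes_macrophages", "T_cells", "T_NK_cells", "B_cells"
)

#' Generate a synthetic study bundle with full ground truth
#'
#' Case sample `j` with necrosis grade `g_j` gets, per gene, `baseline +
#' direction * covariate_effect * g_j + block factor + coupling terms +
#' Gaussian noise`; control samples lack the covariate term but share the
#' block and coupling mechanisms. Identical config (including seed) yields a
#' bit-identical bundle.
#'
#' @param config a [study_config()].
#' @return a list of class `study_bundle` with elements `case`, `control`
#'   (merged [expr_matrix()] objects), `samples`, `annotations`, `targets`,
#'   `seeds` (tibbles) and `truth` (ground-truth list).
#' @export
generate_study <- function(config = study_config()) {
  config <- validate_study_config(config)
  withr::with_seed(config$rng_seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  n_genes <- cfg$n_mirna + cfg$n_mrna
  mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("gene-%04d", seq_len(cfg$n_mrna))
  gene_ids <- c(mirna_ids, mrna_ids)
  species <- c(rep("miRNA", cfg$n_mirna), rep("mRNA", cfg$n_mrna))

  case_ids <- sprintf("ALF_%02d", seq_len(cfg$n_case_samples))
  ctrl_ids <- sprintf("CTRL_%02d", seq_len(cfg$n_control_samples))
  grades <- rep_len(cfg$necrosis_grades, cfg$n_case_samples)

  baseline <- runif(n_genes, 4, 12)

  # direction: -1 hepatocyte (down with necrosis), +1 infiltrate, 0 neutral
  n_hep <- round(cfg$frac_hepatocyte_genes * n_genes)
  n_inf <- n_hep
  dir_codes <- sample(c(rep(-1, n_hep), rep(1, n_inf),
                        rep(0, n_genes - n_hep - n_inf)))
  direction <- c("hepatocyte", "neutral", "infiltrate")[dir_codes + 2]

  # functional blocks on mRNAs only; latent block factor per sample
  block_labels <- rep_len(functional_classes,
                          cfg$n_functional_blocks)[seq_len(cfg$n_functional_blocks)]
  if (cfg$n_functional_blocks > length(functional_classes)) {
    block_labels <- sprintf("block_%02d", seq_len(cfg$n_functional_blocks))
  }
  mrna_block <- sample(rep_len(seq_len(cfg$n_functional_blocks), cfg$n_mrna))
  block_of <- c(rep(NA_integer_, cfg$n_mirna), mrna_block)

  # coupled miRNA-mRNA pairs; signs drawn from the mechanisms with
  # strictly positive strength so couplings=0 configs degenerate cleanly
  pair_idx <- sample(cfg$n_mirna * cfg$n_mrna, cfg$n_target_pairs)
  pair_mirna <- ((pair_idx - 1) %% cfg$n_mirna) + 1
  pair_mrna <- ((pair_idx - 1) %/% cfg$n_mirna) + 1
  avail_signs <- c(if (cfg$inhibitory_coupling > 0) -1,
                   if (cfg$feedforward_coupling > 0) 1)
  if (is.null(avail_signs)) avail_signs <- -1
  pair_sign <- rep_len(avail_signs, cfg$n_target_pairs)

  simulate_condition <- function(n_samples, grades_or_null) {
    m <- matrix(rnorm(n_genes * n_samples, sd = cfg$noise_sd),
                nrow = n_genes) + baseline
    if (!is.null(grades_or_null)) {
      m <- m + outer(dir_codes * cfg$covariate_effect, grades_or_null)
    }
    blockf <- matrix(rnorm(cfg$n_functional_blocks * n_samples),
                     nrow = cfg$n_functional_blocks)
    has_block <- !is.na(block_of)
    m[has_block, ] <- m[has_block, ] +
      cfg$block_effect_sd * blockf[block_of[has_block], , drop = FALSE]
    if (cfg$n_target_pairs > 0) {
      f <- matrix(rnorm(cfg$n_target_pairs * n_samples),
                  nrow = cfg$n_target_pairs)
      for (p in seq_len(cfg$n_target_pairs)) {
        i_mir <- pair_mirna[p]
        i_mr <- cfg$n_mirna + pair_mrna[p]
        if (pair_sign[p] < 0) {
          m[i_mir, ] <- m[i_mir, ] + cfg$inhibitory_coupling * f[p, ]
          m[i_mr, ] <- m[i_mr, ] - cfg$inhibitory_coupling * f[p, ]
        } else {
          m[i_mir, ] <- m[i_mir, ] + cfg$feedforward_coupling * f[p, ]
          m[i_mr, ] <- m[i_mr, ] + cfg$feedforward_coupling * f[p, ]
        }
      }
    }
    m
  }

  case_vals <- simulate_condition(cfg$n_case_samples, grades)
  ctrl_vals <- simulate_condition(cfg$n_control_samples, NULL)
  dimnames(case_vals) <- list(gene_ids, case_ids)
  dimnames(ctrl_vals) <- list(gene_ids, ctrl_ids)

  samples <- tibble::tibble(
    sample_id = c(case_ids, ctrl_ids),
    condition = c(rep("case", cfg$n_case_samples),
                  rep("control", cfg$n_control_samples)),
    necrosis = c(grades, rep(NA_real_, cfg$n_control_samples))
  )

  annotations <- tibble::tibble(
    gene_id = gene_ids,
    species = species,
    functional_class = ifelse(is.na(block_of), NA_character_,
                              block_labels[block_of])
  )

  targets <- tibble::tibble(
    mirna_id = mirna_ids[pair_mirna],
    mrna_id = mrna_ids[pair_mrna],
    mirsvr_score = ifelse(pair_sign < 0, runif(cfg$n_target_pairs, -2, -0.3),
                          runif(cfg$n_target_pairs, -0.3, -0.1)),
    conserved = TRUE
  )

  # synthetic 7-base seeds; n_seed_groups pairs share one
  bases <- c("A", "C", "G", "U")
  draw_seed <- function(n) {
    vapply(seq_len(n), function(i)
      paste(sample(bases, 7, replace = TRUE), collapse = ""), character(1))
  }
  seed_seq <- draw_seed(cfg$n_mirna)
  if (cfg$n_seed_groups > 0) {
    shared <- sample(cfg$n_mirna, 2 * cfg$n_seed_groups)
    for (g in seq_len(cfg$n_seed_groups)) {
      pair <- shared[c(2 * g - 1, 2 * g)]
      seed_seq[pair[2]] <- seed_seq[pair[1]]
    }
  }
  seeds <- tibble::tibble(mirna_id = mirna_ids, seed_sequence = seed_seq)

  truth <- list(
    gene_direction = stats::setNames(direction, gene_ids),
    block_membership = stats::setNames(
      ifelse(is.na(block_of), NA_character_, block_labels[block_of]), gene_ids),
    coupled_pairs = tibble::tibble(
      mirna_id = mirna_ids[pair_mirna],
      mrna_id = mrna_ids[pair_mrna],
      sign = pair_sign
    ),
    baseline_expression = stats::setNames(baseline, gene_ids)
  )

  bundle <- list(
    case = expr_matrix(case_vals, species),
    control = expr_matrix(ctrl_vals, species),
    samples = samples,
    annotations = annotations,
    targets = targets,
    seeds = seeds,
    truth = truth,
    config = cfg
  )
  class(bundle) <- "study_bundle"
  bundle
}

#' Tabular report of the planted structure in a bundle
#'
#' One row per gene with its direction, block, baseline expression and
#' coupling partners (collapsed as `partner:sign` separated by `;`). The
#' report round-trips: [parse_truth_report()] recovers the ground-truth
#' object.
#'
#' @param bundle a [generate_study()] bundle.
#' @return a tibble.
#' @export
truth_report <- function(bundle) {
  tr <- bundle$truth
  pp <- tr$coupled_pairs
  collapse <- function(strings, by) {
    vapply(split(strings, by), paste, character(1), collapse = ";")
  }
  partner_str <- character(0)
  if (nrow(pp) > 0) {
    partner_str <- c(
      collapse(sprintf("%s:%+d", pp$mrna_id, pp$sign), pp$mirna_id),
      collapse(sprintf("%s:%+d", pp$mirna_id, pp$sign), pp$mrna_id)
    )
  }
  ids <- names(tr$gene_direction)
  partners <- unname(partner_str[ids])
  tibble::tibble(
    gene_id = ids,
    direction = unname(tr$gene_direction),
    block = unname(tr$block_membership[ids]),
    baseline = unname(tr$baseline_expression[ids]),
    partners = ifelse(is.na(partners), "", partners)
  )
}

#' Reconstruct the ground-truth object from a truth report
#'
#' @param report a tibble from [truth_report()].
#' @return a ground-truth list as stored in `bundle$truth`.
#' @export
parse_truth_report <- function(report) {
  pairs <- report |>
    dplyr::filter(.data$partners != "") |>
    dplyr::rowwise() |>
    dplyr::reframe(
      gene_id = .data$gene_id,
      entry = strsplit(.data$partners, ";", fixed = TRUE)[[1]]
    ) |>
    tidyr::separate(.data$entry, into = c("partner", "sign"), sep = ":") |>
    dplyr::mutate(sign = as.numeric(.data$sign))
  is_mir <- grepl("^miR", pairs$gene_id)
  coupled <- tibble::tibble(
    mirna_id = ifelse(is_mir, pairs$gene_id, pairs$partner),
    mrna_id = ifelse(is_mir, pairs$partner, pairs$gene_id),
    sign = pairs$sign
  ) |> dplyr::distinct()
  list(
    gene_direction = stats::setNames(report$direction, report$gene_id),
    block_membership = stats::setNames(
      ifelse(is.na(report$block) | report$block == "", NA_character_,
             report$block), report$gene_id),
    coupled_pairs = coupled,
    baseline_expression = stats::setNames(report$baseline, report$gene_id)
  )
}

#' Write / read a study bundle as plain TSV files
#'
#' Files: `case.tsv`, `control.tsv` (gene-id first column, sample header),
#' `samples.tsv`, `annotations.tsv`, `targets.tsv`, `seeds.tsv`, `truth.tsv`.
#'
#' @param bundle a [generate_study()] bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$case, p("case.tsv"), digits = 8)
  write_expression(bundle$control, p("control.tsv"), digits = 8)
  readr::write_tsv(bundle$samples, p("samples.tsv"), progress = FALSE)
  readr::write_tsv(bundle$annotations, p("annotations.tsv"), progress = FALSE)
  readr::write_tsv(bundle$targets, p("targets.tsv"), progress = FALSE)
  readr::write_tsv(bundle$seeds, p("seeds.tsv"), progress = FALSE)
  readr::write_tsv(truth_report(bundle), p("truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_study_bundle
#' @param annotations_path,samples_path optional explicit paths when reading
#'   matrices produced outside [write_study_bundle()].
#' @export
read_study_tables <- function(dir) {
  p <- function(f) file.path(dir, f)
  ann <- readr::read_tsv(p("annotations.tsv"), show_col_types = FALSE)
  species <- stats::setNames(ann$species, ann$gene_id)
  read_tagged <- function(path) {
    x <- read_expression(path, "mRNA")
    x$species <- unname(species[x$gene_id])
    validate_expr_matrix(x)
  }
  list(
    case = read_tagged(p("case.tsv")),
    control = read_tagged(p("control.tsv")),
    samples = readr::read_tsv(p("samples.tsv"), show_col_types = FALSE),
    annotations = ann,
    targets = readr::read_tsv(p("targets.tsv"), show_col_types = FALSE),
    seeds = readr::read_tsv(p("seeds.tsv"), show_col_types = FALSE)
  )
}
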