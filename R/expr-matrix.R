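#' Expression matrix container
#'
#' An `expr_matrix` is a tibble with a `gene_id` column, a `species` column
#' (`"miRNA"` or `"mRNA"`), and one numeric column of log2 expression per
#' sample. All pipeline stages accept and return this shape so calls chain
#' with the pipe.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids) and
#'   colnames (sample ids); or a data frame with `gene_id` as first column.
#' @param species character vector of per-gene tags (`"miRNA"`/`"mRNA"`),
#'   recycled if length 1.
#' @return a tibble of class `expr_matrix`.
#' @export
expr_matrix <- function(values, species) {
  if (is.data.frame(values)) {
    ids <- as.character(values[[1]])
    m <- as.matrix(values[-1])
    rownames(m) <- ids
    values <- m
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  species <- rep_len(as.character(species), nrow(values))
  out <- tibble::tibble(
    gene_id = rownames(values),
    species = species
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values, .name_repair = "minimal"))
  validate_expr_matrix(new_expr_matrix(out))
}

new_expr_matrix <- function(x) {
  class(x) <- c("expr_matrix", class(tibble::tibble()))
  x
}

validate_expr_matrix <- function(x) {
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", ")))
  }
  samp <- expr_samples(x)
  if (length(samp) < 1) abort("expression matrix has no sample columns")
  if (anyDuplicated(samp)) abort("duplicate sample ids in header")
  if (!all(x$species %in% c("miRNA", "mRNA"))) {
    abort("species tags must be 'miRNA' or 'mRNA'")
  }
  v <- expr_values(x)
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite expression value at gene '%s', sample '%s'",
                  rownames(v)[bad[1]], colnames(v)[bad[2]]))
  }
  x
}

#' Accessors for `expr_matrix` objects
#'
#' `expr_values()` returns the numeric genes x samples matrix (with dimnames),
#' `expr_genes()` / `expr_samples()` / `expr_species()` the id and tag vectors.
#'
#' @param x an `expr_matrix`.
#' @name expr-accessors
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), c("gene_id", "species")), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

#' @rdname expr-accessors
#' @export
expr_genes <- function(x) x$gene_id

#' @rdname expr-accessors
#' @export
expr_samples <- function(x) setdiff(names(x), c("gene_id", "species"))

#' @rdname expr-accessors
#' @export
expr_species <- function(x) stats::setNames(x$species, x$gene_id)

#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids. Duplicate gene rows are averaged with a
#' warning (multiple transcripts of the same gene collapse to their mean);
#' non-numeric or missing cells are an error naming the offending cell, since
#' downstream rank correlations assume complete matrices.
#'
#' @param path TSV file path.
#' @param species_tag `"miRNA"` or `"mRNA"`, applied to every gene in the file.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, species_tag = c("mRNA", "miRNA")) {
  species_tag <- match.arg(species_tag)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character(),
                         name_repair = "minimal")
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(sprintf("'%s': empty or sample-less expression file", path))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort(sprintf("'%s': duplicate sample id '%s' in header", path,
                  names(raw)[-1][duplicated(names(raw)[-1])][1]))
  }
  ids <- as.character(raw[[1]])
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, names(raw)[-1]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "'%s': non-numeric cell at gene '%s' (row %d), sample '%s'",
      path, ids[bad[1]], bad[1] + 1L, colnames(num)[bad[2]]))
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warn(sprintf("averaging %d duplicated gene id(s): %s", length(dup),
                 paste(head(dup, 5), collapse = ", ")))
    num <- rowsum(num, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
    ids <- unique(ids)
  }
  rownames(num) <- ids
  expr_matrix(num, species_tag)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 6 significant digits by default, the package's
#' documented round-trip precision.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @param digits significant digits to keep.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, digits = 6) {
  v <- expr_values(x)
  df <- data.frame(gene_id = rownames(v),
                   signif(v, digits), check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Merge miRNA and mRNA profiles into one analysis matrix
#'
#' Stacks the two matrices with miRNAs first, aligning sample columns by id;
#' both inputs must cover exactly the same samples.
#'
#' @param mirna,mrna `expr_matrix` objects over identical sample id sets.
#' @return an `expr_matrix` with both species.
#' @export
merge_profiles <- function(mirna, mrna) {
  s1 <- expr_samples(mirna); s2 <- expr_samples(mrna)
  if (!setequal(s1, s2)) {
    abort(sprintf(
      "sample sets differ; only in first: [%s]; only in second: [%s]",
      paste(setdiff(s1, s2), collapse = ", "),
      paste(setdiff(s2, s1), collapse = ", ")))
  }
  v <- rbind(expr_values(mirna), expr_values(mrna)[, s1, drop = FALSE])
  expr_matrix(v, c(mirna$species, mrna$species))
}

#' Subset an expression matrix to a gene id set
#'
#' @param x an `expr_matrix`.
#' @param id_set character vector of gene ids; the result keeps this order.
#' @return an `expr_matrix` with `length(id_set)` rows.
#' @export
filter_rows <- function(x, id_set) {
  missing <- setdiff(id_set, x$gene_id)
  if (length(missing) > 0) {
    abort(paste0("unknown gene id(s): ", paste(missing, collapse = ", ")))
  }
  idx <- match(id_set, x$gene_id)
  new_expr_matrix(x[idx, , drop = FALSE])
}
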