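# Plain-text readers/writers for the pipeline's external formats: beta and
# expression TSVs (rows = features, columns = samples, NA for missing),
# annotation and clinical TSVs, GMT pathway collections and the ground-truth
# JSON.

#' Read / write a feature-by-sample matrix TSV
#'
#' Tab-separated, first column the feature identifier, one column per
#' sample; missing values written as `NA`. Used for both beta matrices and
#' expression matrices.
#'
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with dimnames.
#' @param id_col header of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe annotation TSV
#'
#' Columns: `probe_id`, `chrom`, `pos`, `strand`, `gene_symbol`, `tss`
#' (0-based coordinates).
#'
#' @param path file path.
#' @export
read_annotation_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_annotation_tsv
#' @param ann annotation data frame.
#' @export
write_annotation_tsv <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway collections and GMT serialization
#'
#' A pathway collection couples a named list of gene sets with the gene
#' universe they are tested against (and optionally a cancer-related
#' subset of pathway ids). `read_gmt_pathways()` parses a GMT file via
#' [fgsea::gmtPathways()]; `write_gmt()` writes one (pathway id, a
#' description placeholder, then genes, tab-separated).
#'
#' @param pathways named list of character gene vectors.
#' @param universe character vector of all candidate genes.
#' @param cancer_related_ids optional subset of `names(pathways)`.
#' @return A list of class `"pathway_collection"`.
#' @export
pathway_collection <- function(pathways, universe, cancer_related_ids = NULL) {
  if (length(pathways) > 0) {
    stray <- setdiff(unique(unlist(pathways)), universe)
    if (length(stray) > 0) {
      stop("pathway genes outside the universe: ", paste(head(stray, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(pathways = pathways, universe = universe,
                 cancer_related_ids = cancer_related_ids),
            class = "pathway_collection")
}

#' @rdname pathway_collection
#' @param path file path.
#' @export
write_gmt <- function(pathways, path) {
  if (inherits(pathways, "pathway_collection")) pathways <- pathways$pathways
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, "na", pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pathway_collection
#' @export
read_gmt_pathways <- function(path, universe = NULL) {
  pw <- if (file.size(path) == 0) list() else fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- sort(unique(unlist(pw)))
  pathway_collection(pw, universe)
}

#' Read / write a clinical table TSV
#'
#' @param path file path.
#' @export
read_clinical_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_clinical_tsv
#' @param clinical clinical data frame.
#' @export
write_clinical_tsv <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore ground truth as JSON
#'
#' Round-trips the planted structure losslessly (up to double precision in
#' the JSON text, written with full precision).
#'
#' @param truth a `"ground_truth"`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    subgroup_of_sample = as.list(truth$subgroup_of_sample),
    key_gene_ids = truth$key_gene_ids,
    planted_module_of_gene = as.list(truth$planted_module_of_gene),
    cancer_module_ids = truth$cancer_module_ids,
    gene_universe = truth$gene_universe,
    true_proportions = list(
      values = unname(as.list(as.data.frame(truth$true_proportions))),
      rows = rownames(truth$true_proportions),
      cols = colnames(truth$true_proportions)
    ),
    true_signature = list(
      values = unname(as.list(as.data.frame(truth$true_signature))),
      rows = rownames(truth$true_signature),
      cols = colnames(truth$true_signature)
    ),
    n_subgroups = truth$n_subgroups
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  # parsed without simplification: jsonlite's auto-simplification of the
  # matrix payload depends on the values themselves
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) vapply(x, as.character, character(1))
  unmat <- function(x) {
    m <- vapply(x$values, function(col) vapply(col, as.numeric, numeric(1)),
                numeric(length(x$rows)))
    dimnames(m) <- list(chr(x$rows), chr(x$cols))
    m
  }
  structure(
    list(
      subgroup_of_sample = stats::setNames(chr(p$subgroup_of_sample),
                                           names(p$subgroup_of_sample)),
      key_gene_ids = chr(p$key_gene_ids),
      planted_module_of_gene = stats::setNames(
        vapply(p$planted_module_of_gene, as.integer, integer(1)),
        names(p$planted_module_of_gene)),
      cancer_module_ids = vapply(p$cancer_module_ids, as.integer, integer(1)),
      gene_universe = chr(p$gene_universe),
      true_proportions = unmat(p$true_proportions),
      true_signature = unmat(p$true_signature),
      n_subgroups = as.integer(p$n_subgroups)
    ),
    class = "ground_truth"
  )
}
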