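#' Construct an expression matrix with sample labels
#'
#' The expression container used throughout the package is a
#' [SummarizedExperiment::SummarizedExperiment] with a single `fpkm` assay
#' (genes x samples, non-negative) and two colData columns: `cohort` and
#' `type_label` (cancer type or tissue).
#'
#' @param values numeric matrix of FPKM values, rownames = gene ids,
#'   colnames = sample ids.
#' @param labels data.frame with columns `sample_id`, `cohort`, `type_label`;
#'   must cover every sample in `values`.
#'
#' @return A `SummarizedExperiment`.
#' @export
expression_matrix <- function(values, labels) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need gene ids as rownames and sample ids as colnames")
  .check_expression_values(values)
  need <- c("sample_id", "cohort", "type_label")
  if (!all(need %in% names(labels)))
    stop("labels must have columns sample_id, cohort, type_label")
  missing <- setdiff(colnames(values), labels$sample_id)
  if (length(missing))
    stop("samples missing from labels: ", paste(missing, collapse = ", "))
  labels <- labels[match(colnames(values), labels$sample_id), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = values),
    colData = S4Vectors::DataFrame(cohort = labels$cohort,
                                   type_label = labels$type_label,
                                   row.names = labels$sample_id))
}

.check_expression_values <- function(values) {
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(is.na(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or missing FPKM at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  invisible(values)
}

#' FPKM assay of an expression matrix
#' @param expr a `SummarizedExperiment` built by [expression_matrix()].
#' @return numeric matrix (genes x samples).
#' @export
fpkm <- function(expr) SummarizedExperiment::assay(expr, "fpkm")

#' Sample labels of an expression matrix
#' @inheritParams fpkm
#' @return data.frame with `sample_id`, `cohort`, `type_label`.
#' @export
sample_labels <- function(expr) {
  cd <- SummarizedExperiment::colData(expr)
  data.frame(sample_id = rownames(cd), cohort = cd$cohort,
             type_label = cd$type_label, stringsAsFactors = FALSE)
}

#' Read an FPKM matrix and its label table from TSV
#'
#' The matrix TSV has a `gene_id` first column and one column per sample; the
#' label TSV has columns `sample_id`, `cohort`, `type_label`. Parsing fails
#' with the offending row or column named when ids are duplicated, labels are
#' missing, or values are negative/NaN.
#'
#' @param path path to the expression TSV.
#' @param labels_path path to the label TSV.
#' @return A `SummarizedExperiment` (see [expression_matrix()]).
#' @export
load_expression <- function(path, labels_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("expression TSV must have 'gene_id' as its first column: ", path)
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- tab$gene_id
  labels <- read.delim(labels_path, stringsAsFactors = FALSE)
  expression_matrix(values, labels)
}

#' Write an FPKM matrix (and optionally its labels) to TSV
#'
#' @inheritParams fpkm
#' @param path output path for the expression TSV.
#' @param labels_path optional output path for the label TSV.
#' @export
write_expression <- function(expr, path, labels_path = NULL) {
  m <- fpkm(expr)
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path))
    write.table(sample_labels(expr), labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Gene sets with filter provenance
#'
#' A `gene_set` is a character vector of gene ids plus the ordered list of
#' filter names that produced it.
#'
#' @param genes character vector of gene ids.
#' @param provenance character vector of applied filter names.
#' @return A `gene_set` object.
#' @export
gene_set <- function(genes, provenance = character()) {
  structure(list(genes = unique(as.character(genes)),
                 provenance = as.character(provenance)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set of %d genes", length(x$genes)))
  if (length(x$provenance))
    cat(" [", paste(x$provenance, collapse = " > "), "]", sep = "")
  cat("\n")
  if (length(x$genes)) cat(" ", paste(head(x$genes, 10), collapse = ", "),
                           if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.gene_set <- function(x, ...) x$genes

#' @export
length.gene_set <- function(x) length(x$genes)

.as_gene_set <- function(x) {
  if (inherits(x, "gene_set")) x else gene_set(x)
}

.append_prov <- function(gs, genes, name) {
  gene_set(genes, c(gs$provenance, name))
}

#' Write a gene set as a TSV with a provenance column
#' @param gs a [gene_set()].
#' @param path output path.
#' @export
write_gene_set <- function(gs, path) {
  prov <- paste(gs$provenance, collapse = ">")
  tab <- data.frame(gene_id = gs$genes,
                    provenance = rep(prov, length(gs$genes)),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
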