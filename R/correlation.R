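#' Sample-sample Pearson correlation over a gene signature
#'
#' Computes pairwise Pearson correlation between samples over
#' `log2(FPKM + 1)` of the signature genes. Samples whose signature vector is
#' constant (zero variance) are flagged and all their correlations — the
#' diagonal included — are set to 0.
#'
#' @param expr expression matrix (see [expression_matrix()]).
#' @param signature a [gene_set()] or character vector; >= 2 genes must be
#'   present in `expr`.
#' @return A `correlation_matrix`: list with `r` (symmetric matrix),
#'   `sample_ids` and `constant_samples`.
#' @export
correlation_matrix <- function(expr, signature) {
  genes <- intersect(as.character(.as_gene_set(signature)$genes),
                     rownames(fpkm(expr)))
  if (length(genes) < 2)
    stop("correlation requires at least two signature genes present in the matrix")
  m <- log2(fpkm(expr)[genes, , drop = FALSE] + 1)
  if (ncol(m) < 2) stop("correlation requires at least two samples")
  sds <- apply(m, 2, sd)
  constant <- colnames(m)[sds == 0]
  r <- suppressWarnings(cor(m))
  r[is.na(r)] <- 0
  diag(r)[!colnames(m) %in% constant] <- 1
  diag(r)[colnames(m) %in% constant] <- 0
  structure(list(r = r, sample_ids = colnames(m), constant_samples = constant),
            class = "correlation_matrix")
}

#' Threshold a correlation matrix into a co-expression network
#'
#' Nodes are all samples (isolated nodes are retained and carry their cohort
#' and type labels); an undirected edge connects two distinct samples when
#' their correlation is at least `r_min` (inclusive), with edge weight `r`.
#' Edge weights are stored rounded to 6 decimals so the graphml round trip
#' is exact.
#'
#' @param cm a [correlation_matrix()].
#' @param labels data.frame with `sample_id`, `cohort`, `type_label`
#'   (e.g. from [sample_labels()]).
#' @param r_min edge threshold (default 0.5, inclusive).
#' @return An [igraph::igraph] graph with vertex attributes `cohort` and
#'   `label`, edge attribute `weight`, and graph attribute `r_min`.
#' @export
build_network <- function(cm, labels, r_min = 0.5) {
  ids <- cm$sample_ids
  labels <- labels[match(ids, labels$sample_id), , drop = FALSE]
  r <- cm$r
  idx <- which(upper.tri(r) & r >= r_min, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = round(r[idx], 6), stringsAsFactors = FALSE)
  vertices <- data.frame(name = ids, cohort = labels$cohort,
                         label = labels$type_label, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "r_min", r_min)
  g
}

#' Connectivity summary of a labelled network
#'
#' @param g graph from [build_network()].
#' @param target_label the type label of interest.
#' @return list with `largest_target_component` (largest number of
#'   target-labelled samples in a single connected component),
#'   `target_component_sizes`, and `cross_label_edges` (edges joining a
#'   target-labelled and a non-target node).
#' @export
component_stats <- function(g, target_label) {
  comp <- igraph::components(g)
  labs <- igraph::vertex_attr(g, "label")
  is_target <- labs == target_label
  per_comp <- tapply(is_target, comp$membership, sum)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  cross <- if (nrow(ends)) sum(is_target[ends[, 1]] != is_target[ends[, 2]]) else 0L
  list(largest_target_component = if (length(per_comp)) max(per_comp) else 0L,
       target_component_sizes = sort(as.integer(per_comp[per_comp > 0]),
                                     decreasing = TRUE),
       cross_label_edges = as.integer(cross))
}

#' Write/read a network in graphml format
#'
#' @param g an igraph graph.
#' @param path graphml file path.
#' @export
write_network <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Per-gene tumor-type specificity t-tests
#'
#' For each gene and each non-target type, a two-sample t test (Welch by
#' default) compares `log2(FPKM + 1)` in target-type samples against that
#' type's samples. Cells whose group has fewer than 2 samples are flagged
#' missing (`NA`). Degenerate zero-variance comparisons are defined as
#' `t = 0, p = 1` when the groups are identical, otherwise `p` collapses to
#' the smallest positive double.
#'
#' @param expr typed expression matrix.
#' @param target_label the target type label.
#' @param genes a [gene_set()] or character vector of genes to test.
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for the pooled test.
#' @return A `specificity_result`: list of matrices `t`, `p`, `neglog10p`
#'   (genes x non-target types).
#' @export
specificity_heatmap <- function(expr, target_label, genes, var_equal = FALSE) {
  gs <- .as_gene_set(genes)
  m <- log2(fpkm(expr) + 1)
  lab <- sample_labels(expr)
  genes <- intersect(gs$genes, rownames(m))
  if (!length(genes)) stop("no signature genes present in the matrix")
  if (sum(lab$type_label == target_label) < 2)
    stop("need >= 2 target-type samples")
  types <- setdiff(unique(lab$type_label), target_label)
  tmat <- pmat <- matrix(NA_real_, length(genes), length(types),
                         dimnames = list(genes, types))
  tv <- m[, lab$type_label == target_label, drop = FALSE]
  for (tt in types) {
    ov <- m[, lab$type_label == tt, drop = FALSE]
    if (ncol(ov) < 2) next  # flagged missing: fewer than 2 samples
    for (gn in genes) {
      res <- .welch_safe(tv[gn, ], ov[gn, ], var_equal)
      tmat[gn, tt] <- res$t
      pmat[gn, tt] <- res$p
    }
  }
  structure(list(t = tmat, p = pmat, neglog10p = -log10(pmat)),
            class = "specificity_result")
}

.welch_safe <- function(x, y, var_equal = FALSE) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = .Machine$double.xmin))
  }
  res <- t.test(x, y, var.equal = var_equal)
  list(t = unname(res$statistic), p = res$p.value)
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("specificity_result: %d genes x %d types (-log10 p, two-sample t)\n",
              nrow(x$t), ncol(x$t)))
  invisible(x)
}

#' Write the -log10 p matrix of a specificity result as TSV
#' @param sr a `specificity_result`.
#' @param path output path.
#' @export
write_specificity <- function(sr, path) {
  tab <- data.frame(gene_id = rownames(sr$neglog10p), sr$neglog10p,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
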