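#' Genes commonly regulated across knockdown experiments
#'
#' Intersects the per-experiment regulated gene lists: for
#' `direction = "down"` a gene is kept when, in \emph{every} control/knockdown
#' pair, its control FPKM exceeds `min_expr` (strict) and
#' `(ctrl + eps) / (kd + eps) >= min_fold` (inclusive). `direction = "up"` is
#' symmetric, gating on the knockdown FPKM and the inverted ratio. The
#' strict/inclusive mix mirrors the usual statement of such filters:
#' expression gates are ">1 FPKM", fold gates are ">=2-fold".
#'
#' @param kd expression matrix (see [expression_matrix()]) holding all
#'   control and knockdown samples.
#' @param pairs data.frame with columns `ctrl` and `kd` naming the sample
#'   pair of each knockdown experiment.
#' @param direction `"down"` (fusion-activated genes) or `"up"`
#'   (fusion-repressed genes).
#' @param min_expr FPKM expression gate (default 1, strict `>`).
#' @param min_fold fold-change gate (default 2, inclusive `>=`); must be
#'   >= 1.
#' @param pseudocount FPKM added to numerator and denominator so the ratio is
#'   finite (default 0.01).
#' @return A [gene_set()] with provenance `common_down` or `common_up`.
#' @export
common_regulated <- function(kd, pairs, direction = c("down", "up"),
                             min_expr = 1, min_fold = 2, pseudocount = 0.01) {
  direction <- match.arg(direction)
  if (nrow(pairs) < 1) stop("at least one control/knockdown pair is required")
  if (min_fold < 1) stop("min_fold must be >= 1")
  m <- fpkm(kd)
  unknown <- setdiff(c(pairs$ctrl, pairs$kd), colnames(m))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(pairs))) {
    ctrl <- m[, pairs$ctrl[i]]
    kdv <- m[, pairs$kd[i]]
    if (direction == "down") {
      pass <- ctrl > min_expr & (ctrl + pseudocount) / (kdv + pseudocount) >= min_fold
    } else {
      pass <- kdv > min_expr & (kdv + pseudocount) / (ctrl + pseudocount) >= min_fold
    }
    keep <- keep & pass
  }
  gene_set(rownames(m)[keep], paste0("common_", direction))
}

#' Log2 fold-change table for knockdown experiments
#'
#' Companion report to [common_regulated()]: per-experiment
#' `log2((ctrl + eps) / (kd + eps))` ("down" orientation) together with the
#' control FPKM.
#'
#' @inheritParams common_regulated
#' @return data.frame with `gene_id` and, per experiment, `log2fc_*` and
#'   `ctrl_fpkm_*` columns.
#' @export
fold_change_table <- function(kd, pairs, pseudocount = 0.01) {
  m <- fpkm(kd)
  out <- data.frame(gene_id = rownames(m), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    ctrl <- m[, pairs$ctrl[i]]
    kdv <- m[, pairs$kd[i]]
    out[[paste0("log2fc_", pairs$ctrl[i])]] <-
      log2((ctrl + pseudocount) / (kdv + pseudocount))
    out[[paste0("ctrl_fpkm_", pairs$ctrl[i])]] <- ctrl
  }
  out
}

#' Cell-line specificity filter
#'
#' Removes every candidate expressed above `max_fpkm` (strict `>`) in at
#' least one sample whose `type_label` differs from `target_type` — the
#' "expressed in any non-target cell line" screen. Target-type lines inside
#' the cohort are excluded from the screen by their label.
#'
#' @param candidates a [gene_set()] (or character vector).
#' @param lines typed pan-cancer cell-line expression matrix.
#' @param target_type the fusion-driven type label (e.g. `"EwS"`).
#' @param max_fpkm tolerated off-target FPKM (default 1, strict `>` removes).
#' @return Filtered [gene_set()], provenance appended.
#' @export
specificity_filter_lines <- function(candidates, lines, target_type, max_fpkm = 1) {
  gs <- .as_gene_set(candidates)
  lab <- sample_labels(lines)
  if (!target_type %in% lab$type_label)
    stop("target_type '", target_type, "' not present among cell-line labels")
  if (!length(gs$genes)) return(.append_prov(gs, character(0), "lines_specific"))
  m <- fpkm(lines)
  genes <- intersect(gs$genes, rownames(m))
  off <- m[genes, lab$type_label != target_type, drop = FALSE]
  keep <- if (ncol(off) == 0) genes else genes[apply(off, 1, max) <= max_fpkm]
  .append_prov(gs, keep, "lines_specific")
}

#' Tumor-type specificity filter
#'
#' A cancer type "expresses" a gene when the `type_stat` of its samples'
#' FPKM exceeds `fpkm_thr` (strict `>`). Genes expressed in more than
#' `max_other_types` types — counting all types, including the target type —
#' are removed; the default `max_other_types = 1` realizes the "discard genes
#' expressed in more than one cancer type" rule.
#'
#' @inheritParams specificity_filter_lines
#' @param cohort typed expression matrix with >= 2 type labels.
#' @param target_type optional; validated to be a known label when given
#'   (the rule itself counts all types).
#' @param fpkm_thr type-level expression threshold (default 1).
#' @param max_other_types maximum number of expressing types tolerated
#'   (default 1).
#' @param type_stat how a type's expression is summarized: `"median"`
#'   (default, robust to single-sample outliers), `"mean"`, or `"any"`
#'   (any single sample above threshold).
#' @return Filtered [gene_set()], provenance appended.
#' @export
specificity_filter_types <- function(candidates, cohort, target_type = NULL,
                                     fpkm_thr = 1, max_other_types = 1,
                                     type_stat = c("median", "mean", "any")) {
  type_stat <- match.arg(type_stat)
  gs <- .as_gene_set(candidates)
  lab <- sample_labels(cohort)
  if (length(unique(lab$type_label)) < 2)
    stop("cohort must carry at least two type labels")
  if (!length(gs$genes)) return(.append_prov(gs, character(0), "type_specific"))
  m <- fpkm(cohort)
  genes <- intersect(gs$genes, rownames(m))
  n_types <- .expressing_type_count(m[genes, , drop = FALSE], lab$type_label,
                                    fpkm_thr, type_stat)
  .append_prov(gs, genes[n_types <= max_other_types], "type_specific")
}

.expressing_type_count <- function(m, type_label, fpkm_thr, type_stat) {
  stat_fun <- switch(type_stat,
                     median = function(x) median(x),
                     mean = function(x) mean(x),
                     any = function(x) max(x))
  expressed <- vapply(unique(type_label), function(tt) {
    sub <- m[, type_label == tt, drop = FALSE]
    apply(sub, 1, stat_fun) > fpkm_thr
  }, logical(nrow(m)))
  if (is.null(dim(expressed))) expressed <- matrix(expressed, nrow = 1)
  rowSums(expressed)
}

#' Normal-tissue screen
#'
#' Annotates — without silently dropping — each candidate with the number
#' and identity of normal tissues expressing it (tissue `type_stat` median
#' FPKM above `fpkm_thr`), and flags genes expressed in more than
#' `max_tissues` tissues. Downstream callers decide whether flagged genes
#' are excluded.
#'
#' @inheritParams specificity_filter_types
#' @param normals typed normal-tissue expression matrix.
#' @param max_tissues tissues tolerated before a gene is flagged
#'   (default 1: a single-tissue, testis-restricted-style pattern passes).
#' @return list with `genes` (the input [gene_set()], provenance appended)
#'   and `report` (per-gene `n_tissues`, comma-separated `tissues`,
#'   `flagged`).
#' @export
tissue_screen <- function(candidates, normals, fpkm_thr = 1, max_tissues = 1,
                          type_stat = c("median", "mean", "any")) {
  type_stat <- match.arg(type_stat)
  gs <- .as_gene_set(candidates)
  lab <- sample_labels(normals)
  m <- fpkm(normals)
  genes <- intersect(gs$genes, rownames(m))
  tissues <- unique(lab$type_label)
  stat_fun <- switch(type_stat, median = median, mean = mean, any = max)
  expressed <- vapply(tissues, function(tt) {
    sub <- m[genes, lab$type_label == tt, drop = FALSE]
    apply(sub, 1, stat_fun) > fpkm_thr
  }, logical(length(genes)))
  if (is.null(dim(expressed)))
    expressed <- matrix(expressed, nrow = length(genes),
                        dimnames = list(genes, tissues))
  report <- data.frame(
    gene_id = genes,
    n_tissues = rowSums(expressed),
    tissues = apply(expressed, 1, function(z) paste(tissues[z], collapse = ",")),
    stringsAsFactors = FALSE)
  report$flagged <- report$n_tissues > max_tissues
  rownames(report) <- NULL
  list(genes = .append_prov(gs, gs$genes, "tissue_screen"), report = report)
}
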