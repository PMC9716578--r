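#' Single-base interval overlap
#'
#' Two 0-based half-open intervals overlap when they share at least one base
#' — the "single base" convention used for peak overlap throughout the
#' package. Comparing intervals from different chromosomes is the caller's
#' responsibility.
#'
#' @param a,b numeric vectors `c(start, end)` with `start < end`, 0-based
#'   half-open.
#' @return `TRUE` iff the intersection is at least 1 bp.
#' @examples
#' intervals_overlap(c(100, 200), c(199, 300))  # TRUE: one shared base
#' intervals_overlap(c(100, 200), c(200, 300))  # FALSE: half-open abutment
#' @export
intervals_overlap <- function(a, b) {
  if (a[1] >= a[2] || b[1] >= b[2])
    stop("malformed interval: start must be < end")
  min(a[2], b[2]) - max(a[1], b[1]) >= 1
}

#' Read/write BED6 peak files
#'
#' Peaks are represented as data.frames with 0-based half-open `start`/`end`,
#' matching BED coordinates on disk.
#'
#' @param path BED file path.
#' @return `read_bed`: data.frame with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else sprintf("peak%d", seq_along(gr)),
             score = if (!is.null(gr$score)) gr$score else 0L,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param peaks peak data.frame as returned by `read_bed` or the generator.
#' @export
write_bed <- function(peaks, path) {
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "."
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end),
    strand = strand,
    name = peaks$name,
    score = if ("score" %in% names(peaks)) peaks$score else 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Assign peaks to genes by a TSS window
#'
#' A peak is assigned to a gene when it overlaps (by at least one base) the
#' window `[tss - window_bp, tss + window_bp + 1)` on the same chromosome, so
#' a peak touching exactly +/-`window_bp` from the TSS still counts as
#' "within". Gene strand is ignored; a peak may be assigned to several genes.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `name`, 0-based
#'   half-open).
#' @param ann annotation data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @param window_bp half-width of the TSS window in bp (default 100000,
#'   i.e. the +/-100 kb direct-target rule).
#' @param chrom_sizes optional named vector of known chromosome lengths; a
#'   warning names genes annotated on chromosomes absent from it.
#' @return Named list mapping every `gene_id` to the character vector of
#'   assigned peak names (possibly empty).
#' @export
assign_peaks_to_tss <- function(peaks, ann, window_bp = 100000, chrom_sizes = NULL) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (any(peaks$start >= peaks$end))
    stop("malformed interval: start must be < end")
  if (!is.null(chrom_sizes)) {
    lost <- ann$gene_id[!ann$chrom %in% names(chrom_sizes)]
    if (length(lost))
      warning("genes on chromosomes missing from the genome, assigned nothing: ",
              paste(lost, collapse = ", "))
  }
  out <- setNames(vector("list", nrow(ann)), ann$gene_id)
  for (chrom in unique(ann$chrom)) {
    p <- peaks[peaks$chrom == chrom, , drop = FALSE]
    g <- which(ann$chrom == chrom)
    for (i in g) {
      ws <- ann$tss[i] - window_bp
      we <- ann$tss[i] + window_bp + 1   # half-open; +window_bp base included
      hit <- p$start < we & p$end > ws
      out[[ann$gene_id[i]]] <- p$name[hit]
    }
  }
  for (i in seq_along(out)) if (is.null(out[[i]])) out[[i]] <- character(0)
  out
}

#' Keep candidate genes with at least one assigned peak
#'
#' @param candidates a [gene_set()] (or character vector).
#' @param assignment gene -> peak-name map from [assign_peaks_to_tss()].
#' @return The [gene_set()] of candidates with >= 1 assigned peak,
#'   provenance appended.
#' @export
direct_targets <- function(candidates, assignment) {
  gs <- .as_gene_set(candidates)
  with_peak <- names(assignment)[lengths(assignment) > 0]
  .append_prov(gs, intersect(gs$genes, with_peak), "direct_target")
}
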