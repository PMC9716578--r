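#' Coverage tracks and tag-density profiles
#'
#' A `coverage_track` holds non-overlapping, sorted, 0-based half-open step
#' intervals with a non-negative per-bp value, plus the track's library size
#' (total tags), the denominator of reads-per-million normalization.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param library_size total tag count; defaults to the track's own total
#'   signal `sum(value * width)`. Pre-normalized tracks may declare `1e6`.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(intervals, library_size = NULL) {
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(intervals)))
    stop("coverage intervals need columns chrom, start, end, value")
  if (any(intervals$start >= intervals$end))
    stop("coverage intervals must satisfy start < end")
  if (any(intervals$value < 0))
    stop("coverage values must be >= 0")
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  for (chrom in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop("coverage intervals overlap on ", chrom)
  }
  rownames(intervals) <- NULL
  if (is.null(library_size))
    library_size <- sum((intervals$end - intervals$start) * intervals$value)
  structure(list(intervals = intervals, library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d intervals on %d chromosome(s), library size %.4g\n",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              x$library_size))
  invisible(x)
}

#' Read/write a coverage track as bedGraph
#'
#' The library size of a track read from disk is its own total signal
#' (consistent with tracks normalized per million by their producer declaring
#' `library_size = 1e6` explicitly via [coverage_track()]).
#'
#' @param path bedGraph file path.
#' @return `read_bedgraph`: a [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score,
    stringsAsFactors = FALSE))
}

#' @rdname read_bedgraph
#' @param track a [coverage_track()].
#' @export
write_bedgraph <- function(track, path) {
  iv <- track$intervals
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(iv$start + 1L, iv$end),
                               score = iv$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Total tag density (rpm) over regions with flanks
#'
#' For each region, sums the raw coverage over `[start - flank_bp,
#' end + flank_bp)` (clipped to the chromosome when `chrom_sizes` is given)
#' and scales to reads per million by the track's library size.
#'
#' @param track a [coverage_track()] with `library_size > 0`.
#' @param regions peak data.frame (`chrom`, `start`, `end`, `name`; 0-based
#'   half-open).
#' @param flank_bp half-open flank added to each side (default 2500, the
#'   +/-2.5 kb window of the tag-density metaprofile).
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   clip flanks.
#' @return data.frame with per-region `raw` coverage sums and `rpm`.
#' @export
tag_density <- function(track, regions, flank_bp = 2500, chrom_sizes = NULL) {
  if (!inherits(track, "coverage_track")) stop("track must be a coverage_track")
  if (track$library_size <= 0) stop("tag_density: library_size must be > 0")
  iv <- track$intervals
  raw <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i] - flank_bp
    e <- regions$end[i] + flank_bp
    if (!is.null(chrom_sizes) && regions$chrom[i] %in% names(chrom_sizes)) {
      s <- max(s, 0)
      e <- min(e, chrom_sizes[[regions$chrom[i]]])
    }
    sub <- iv[iv$chrom == regions$chrom[i] & iv$start < e & iv$end > s, , drop = FALSE]
    if (nrow(sub))
      raw[i] <- sum((pmin(sub$end, e) - pmax(sub$start, s)) * sub$value)
  }
  data.frame(name = regions$name, chrom = regions$chrom,
             start = regions$start, end = regions$end,
             raw = raw, rpm = raw / track$library_size * 1e6,
             stringsAsFactors = FALSE)
}
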