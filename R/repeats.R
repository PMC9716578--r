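#' Maximal tandem-repeat run of a motif
#'
#' Counts the longest run of exact, uninterrupted tandem copies of `motif`
#' in `seq`. With `both_strands = TRUE` the reverse complement is scanned as
#' well and the larger run is returned with its strand (ties broken toward
#' `"+"`). Only exact copies count — no mismatch tolerance — and `N` never
#' matches.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @param motif repeat unit (default `"GGAA"`, the microsatellite bound by
#'   EWSR1::ETS oncofusions).
#' @param both_strands also scan the reverse complement (default `TRUE`;
#'   fusion binding is strand-agnostic).
#' @return list with `max_run` (count of consecutive copies, 0 for an empty
#'   or motif-free sequence) and `strand` (`"+"` or `"-"`).
#' @examples
#' max_tandem_repeat("GGAAGGAAGGAA")$max_run          # 3
#' max_tandem_repeat("TTCCTTCCTTCCTTCCTTCC")$strand   # "-"
#' @export
max_tandem_repeat <- function(seq, motif = "GGAA", both_strands = TRUE) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  seq <- toupper(as.character(seq))
  fwd <- .max_run_one_strand(seq, motif)
  if (!both_strands) return(list(max_run = fwd, strand = "+"))
  rev <- .max_run_one_strand(seq, .revcomp_string(motif))
  if (rev > fwd) list(max_run = rev, strand = "-")
  else list(max_run = fwd, strand = "+")
}

# Longest chain of motif occurrences at stride nchar(motif). Occurrence
# starts come from Biostrings::matchPattern (overlap-aware), then each of the
# nchar(motif) frame classes is run-length scanned.
.max_run_one_strand <- function(seq, motif) {
  k <- nchar(motif)
  n <- nchar(seq)
  if (n < k) return(0L)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq), fixed = TRUE)
  starts <- IRanges::start(hits)
  if (!length(starts)) return(0L)
  occ <- logical(n - k + 1L)
  occ[starts] <- TRUE
  best <- 0L
  for (off in seq_len(min(k, length(occ)))) {
    frame <- occ[seq.int(off, length(occ), by = k)]
    r <- rle(frame)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  as.integer(best)
}

#' Annotate peaks with their maximal motif run
#'
#' Extracts each peak's sequence (optionally extended by `flank_bp`, clipped
#' to the chromosome) and records the maximal tandem run of `motif` via
#' [max_tandem_repeat()], plus the fraction of peaks whose run reaches
#' `min_repeats` — the summary behind "fraction of fusion-bound regions with
#' at least five consecutive GGAA repeats".
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `name`; 0-based
#'   half-open).
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param motif repeat unit.
#' @param min_repeats run-count threshold for the summary fraction
#'   (default 5).
#' @param flank_bp extra sequence scanned on each side of the peak
#'   (default 0: the peak interval exactly).
#' @param both_strands passed to [max_tandem_repeat()].
#' @return A `repeat_annotation`: list with `regions` (per-peak `max_run`,
#'   `strand_of_max`), `min_repeats`, and `fraction_ge_threshold`.
#' @export
annotate_repeats <- function(peaks, genome, motif = "GGAA", min_repeats = 5,
                             flank_bp = 0, both_strands = TRUE) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  max_run <- integer(nrow(peaks))
  strand <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome))
      stop(sprintf("peak '%s' lies on unknown chromosome '%s'", peaks$name[i], chrom))
    len <- nchar(genome[[chrom]])
    if (peaks$start[i] < 0 || peaks$end[i] > len)
      stop(sprintf("peak '%s' exceeds chromosome '%s' bounds [0, %d)",
                   peaks$name[i], chrom, len))
    s <- max(0, peaks$start[i] - flank_bp)
    e <- min(len, peaks$end[i] + flank_bp)
    res <- max_tandem_repeat(substr(genome[[chrom]], s + 1L, e), motif, both_strands)
    max_run[i] <- res$max_run
    strand[i] <- res$strand
  }
  regions <- data.frame(name = peaks$name, chrom = peaks$chrom,
                        start = peaks$start, end = peaks$end,
                        max_run = max_run, strand_of_max = strand,
                        stringsAsFactors = FALSE)
  structure(list(regions = regions, min_repeats = min_repeats,
                 fraction_ge_threshold = mean(max_run >= min_repeats)),
            class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat(sprintf("repeat_annotation: %d regions, %.1f%% with >= %d consecutive copies\n",
              nrow(x$regions), 100 * x$fraction_ge_threshold, x$min_repeats))
  invisible(x)
}

#' Write a repeat annotation as TSV
#' @param ra a `repeat_annotation` from [annotate_repeats()].
#' @param path output path.
#' @export
write_repeat_annotation <- function(ra, path) {
  write.table(ra$regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
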