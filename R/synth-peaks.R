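# Deterministic genome layout shared by make_genome() and
# make_peaks_and_tracks(): chromosome assignment, per-gene slot widths, TSS
# coordinates and chromosome lengths. Uses only the planted-gene draw of the
# generator RNG stream.
.genome_layout <- function(cfg) {
  planted <- .planted_idx(cfg)
  is_planted <- seq_len(cfg$n_genes) %in% planted
  chrom_of <- sprintf("chr%d", ceiling(seq_len(cfg$n_genes) / cfg$genes_per_chrom))
  slot_len <- ifelse(is_planted, 2 * cfg$planted_isolation_bp, cfg$genome_len_per_gene)
  tss <- integer(cfg$n_genes)
  chrom_len <- integer(0)
  for (chrom in unique(chrom_of)) {
    idx <- which(chrom_of == chrom)
    starts <- cumsum(c(0, slot_len[idx][-length(idx)]))
    tss[idx] <- as.integer(starts + slot_len[idx] %/% 2)
    chrom_len[chrom] <- sum(slot_len[idx])
  }
  chrom_len["chrD"] <- as.integer((cfg$n_decoy_peaks + 1L) * 2000L)
  list(planted = planted, chrom_of = chrom_of, tss = tss, chrom_len = chrom_len)
}

#' Generate fusion-conditional peak sets and coverage tracks
#'
#' Builds two peak sets and two matched coverage tracks:
#' \describe{
#'   \item{fusion_on}{one peak over every planted repeat region (so the
#'     direct-target rule fires for every planted gene) plus decoy peaks on a
#'     gene-free chromosome, more than 100 kb from every TSS.}
#'   \item{fusion_off}{the decoy peaks only.}
#' }
#' The coverage tracks carry a flat background of `track_background` per bp
#' and gain `track_peak_gain` per bp within `flank_signal_bp` of the active
#' peaks of their condition (planted regions are active only under
#' `fusion_on`; decoys are active under both, emulating fusion-independent
#' regulatory elements). Each track's library size is its own total signal,
#' the denominator for rpm normalization.
#'
#' @param cfg a [synth_config()].
#' @param annotation gene annotation from [make_genome()].
#' @param truth ground-truth record from [make_genome()].
#' @return A list with `peaks` (named list of peak data.frames, 0-based
#'   half-open) and `tracks` (named list of [coverage_track()]s).
#' @export
make_peaks_and_tracks <- function(cfg, annotation, truth) {
  cfg <- validate_synth_config(cfg)
  layout <- .genome_layout(cfg)
  regions <- truth$planted_repeat_regions

  planted_peaks <- data.frame(
    chrom = regions$chrom,
    start = regions$start - cfg$peak_margin_bp,
    end = regions$end + cfg$peak_margin_bp,
    name = sprintf("peak_%s", regions$gene_id),
    score = 100L,
    strand = ".",
    stringsAsFactors = FALSE)

  decoys <- data.frame(
    chrom = "chrD",
    start = seq_len(cfg$n_decoy_peaks) * 2000L,
    end = seq_len(cfg$n_decoy_peaks) * 2000L + 400L,
    name = sprintf("decoy%02d", seq_len(cfg$n_decoy_peaks)),
    score = 100L,
    strand = ".",
    stringsAsFactors = FALSE)

  fusion_on <- .sort_peaks(rbind(planted_peaks, decoys))
  fusion_off <- .sort_peaks(decoys)

  tracks <- list(
    fusion_on = .build_track(layout$chrom_len, fusion_on,
                             cfg$track_background, cfg$track_peak_gain,
                             cfg$flank_signal_bp),
    fusion_off = .build_track(layout$chrom_len, fusion_off,
                              cfg$track_background, cfg$track_peak_gain,
                              cfg$flank_signal_bp))

  list(peaks = list(fusion_on = fusion_on, fusion_off = fusion_off),
       tracks = tracks)
}

.sort_peaks <- function(p) {
  p <- p[order(p$chrom, p$start, p$name), , drop = FALSE]
  rownames(p) <- NULL
  p
}

# Piecewise-constant coverage: background everywhere, elevated over the
# (merged, clipped) active windows.
.build_track <- function(chrom_len, active_peaks, background, gain, flank) {
  out <- list()
  for (chrom in names(chrom_len)) {
    len <- chrom_len[[chrom]]
    win <- active_peaks[active_peaks$chrom == chrom, , drop = FALSE]
    if (nrow(win) == 0) {
      out[[chrom]] <- data.frame(chrom = chrom, start = 0, end = len,
                                 value = background, stringsAsFactors = FALSE)
      next
    }
    s <- pmax(0L, win$start - flank)
    e <- pmin(len, win$end + flank)
    o <- order(s)
    s <- s[o]; e <- e[o]
    # merge overlapping windows
    ms <- s[1]; me <- e[1]; merged_s <- c(); merged_e <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) me <- max(me, e[i]) else {
        merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
    bounds <- sort(unique(c(0, merged_s, merged_e, len)))
    seg_s <- bounds[-length(bounds)]
    seg_e <- bounds[-1]
    elevated <- vapply(seg_s, function(p) any(merged_s <= p & p < merged_e), logical(1))
    out[[chrom]] <- data.frame(chrom = chrom, start = seg_s, end = seg_e,
                               value = background + ifelse(elevated, gain, 0),
                               stringsAsFactors = FALSE)
  }
  intervals <- do.call(rbind, out)
  rownames(intervals) <- NULL
  coverage_track(intervals)
}
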