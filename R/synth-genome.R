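#' Generate a synthetic genome with planted microsatellite runs
#'
#' Builds one random chromosome per block of `genes_per_chrom` genes plus one
#' gene-free decoy chromosome, lays out a TSS for every gene, and plants, for
#' each planted target gene, a run of exactly `planted_repeat_len` consecutive
#' copies of the GGAA motif `peak_window_offset_bp` upstream of its TSS.
#' Background sequence is rejection-sampled so that it contains no run of 3 or
#' more motif copies on either strand; the planted runs are therefore the only
#' microsatellite expansions in the genome, and every planted region's maximal
#' run equals `planted_repeat_len` exactly (the run is insulated by
#' non-motif bases on both sides).
#'
#' Planted genes sit in isolated slots (`planted_isolation_bp` of gene-free
#' sequence on each side) so that no other gene's TSS falls within the
#' +/-100 kb direct-target window of a planted regulatory region; background
#' genes are packed at `genome_len_per_gene` spacing.
#'
#' @param cfg a [synth_config()].
#' @param max_tries bounded number of rejection-sampling rounds per
#'   chromosome before generation fails.
#'
#' @return A list with elements
#'   \item{genome}{named character vector of chromosome sequences,}
#'   \item{annotation}{data.frame with `gene_id`, `chrom`, `tss` (0-based)
#'     and `strand`,}
#'   \item{truth}{partial ground truth: `planted_target_genes`,
#'     `planted_repeat_regions` (0-based half-open intervals) and
#'     `planted_repeat_counts`.}
#' @export
make_genome <- function(cfg, max_tries = 20L) {
  cfg <- validate_synth_config(cfg)
  layout <- .genome_layout(cfg)
  planted <- layout$planted
  chrom_of <- layout$chrom_of
  tss <- layout$tss
  chrom_len <- layout$chrom_len
  ids <- .gene_ids(cfg)

  set.seed(.sub_seed(cfg$seed, 1L))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

  raw_genome <- lapply(setNames(names(chrom_len), names(chrom_len)), function(chrom) {
    .clean_background(.random_dna_raw(chrom_len[[chrom]]), max_tries, chrom)
  })

  # plant the repeat runs and insulate them so the maximal run is exact
  run_len <- 4L * cfg$planted_repeat_len
  rep_start <- tss[planted] - cfg$peak_window_offset_bp
  run_bytes <- charToRaw(strrep("GGAA", cfg$planted_repeat_len))
  c_byte <- charToRaw("C")
  for (k in seq_along(planted)) {
    chrom <- chrom_of[planted[k]]
    s <- rep_start[k]                      # 0-based
    raw_genome[[chrom]][(s + 1L):(s + run_len)] <- run_bytes
    if (s >= 1L) raw_genome[[chrom]][s] <- c_byte          # base before the run
    raw_genome[[chrom]][s + run_len + 1L] <- c_byte        # base after
  }
  genome <- vapply(raw_genome, rawToChar, character(1))

  annotation <- data.frame(gene_id = ids, chrom = chrom_of, tss = tss,
                           strand = strand, stringsAsFactors = FALSE)
  regions <- data.frame(
    name = sprintf("rep_%s", ids[planted]),
    chrom = chrom_of[planted],
    start = rep_start,
    end = rep_start + run_len,
    gene_id = ids[planted],
    stringsAsFactors = FALSE)
  truth <- list(
    planted_target_genes = ids[planted],
    planted_repeat_regions = regions,
    planted_repeat_counts = setNames(rep(cfg$planted_repeat_len, nrow(regions)),
                                     regions$name))
  list(genome = genome, annotation = annotation, truth = truth)
}

.random_dna_raw <- function(len) {
  alphabet <- charToRaw("ACGT")
  alphabet[sample.int(4L, len, replace = TRUE)]
}

.random_dna <- function(len) rawToChar(.random_dna_raw(len))

# Redraw every background stretch holding >=3 consecutive GGAA copies on
# either strand (a reverse-strand run reads TTCC... forward) until none
# remain. A run of >= 3 copies necessarily contains the 12-mer triple, so
# Boyer-Moore search for the two triples finds every offending stretch.
.clean_background <- function(x, max_tries, chrom) {
  triples <- list(Biostrings::DNAString(strrep("GGAA", 3)),
                  Biostrings::DNAString(strrep("TTCC", 3)))
  for (i in seq_len(max_tries + 1L)) {
    subject <- Biostrings::DNAString(rawToChar(x))
    bad <- unlist(lapply(triples, function(p)
      IRanges::start(Biostrings::matchPattern(p, subject, fixed = TRUE))))
    if (!length(bad)) return(x)
    if (i > max_tries) break
    idx <- unique(as.vector(outer(bad, 0:11, `+`)))
    x[idx] <- .random_dna_raw(length(idx))
  }
  stop(sprintf("background generation failed on chromosome '%s' after %d rejection rounds",
               chrom, max_tries))
}

.revcomp_string <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
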