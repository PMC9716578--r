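#' Build the full synthetic dataset in memory
#'
#' Runs [make_genome()], [make_cohorts()] and [make_peaks_and_tracks()] under
#' one configuration and merges their ground-truth records.
#'
#' @param cfg a [synth_config()].
#' @return A `synth_dataset` bundle: `config`, `genome`, `annotation`,
#'   `cohorts`, `pairs`, `peaks`, `tracks`, `truth`.
#' @export
make_synth_dataset <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  gen <- make_genome(cfg)
  coh <- make_cohorts(cfg)
  pt <- make_peaks_and_tracks(cfg, gen$annotation, gen$truth)
  structure(list(config = cfg,
                 genome = gen$genome,
                 annotation = gen$annotation,
                 cohorts = coh$cohorts,
                 pairs = coh$pairs,
                 peaks = pt$peaks,
                 tracks = pt$tracks,
                 truth = gen$truth),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset: %d genes (%d planted), %d chromosomes, %d cohorts\n",
              x$config$n_genes, x$config$n_planted_targets,
              length(x$genome), length(x$cohorts)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard plain-text artifacts: `genome.fa`, `annotation.tsv`
#' (gene_id, chrom, tss_0based, strand), `chrom_sizes.tsv`, one `<cohort>.tsv`
#' FPKM matrix per cohort plus a shared `labels.tsv`, `kd_pairs.tsv`,
#' `peaks_<condition>.bed`, `coverage_<condition>.bedGraph` and
#' `ground_truth.json`. Identical configurations (seed included) produce
#' byte-identical files.
#'
#' @param cfg a [synth_config()], or a prebuilt `synth_dataset`.
#' @param outdir output directory (created if absent).
#' @return Invisibly, the in-memory `synth_dataset`.
#' @export
write_synth_dataset <- function(cfg, outdir) {
  ds <- if (inherits(cfg, "synth_dataset")) cfg else make_synth_dataset(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$genome), p("genome.fa"))
  ann <- ds$annotation
  names(ann)[names(ann) == "tss"] <- "tss_0based"
  write.table(ann, p("annotation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = names(ds$genome), length = nchar(ds$genome)),
              p("chrom_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  labels <- do.call(rbind, lapply(ds$cohorts, sample_labels))
  rownames(labels) <- NULL
  write.table(labels, p("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(ds$cohorts))
    write_expression(ds$cohorts[[nm]], p(paste0(nm, ".tsv")))
  write.table(ds$pairs, p("kd_pairs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  for (cond in names(ds$peaks))
    write_bed(ds$peaks[[cond]], p(paste0("peaks_", cond, ".bed")))
  for (cond in names(ds$tracks))
    write_bedgraph(ds$tracks[[cond]], p(paste0("coverage_", cond, ".bedGraph")))

  jsonlite::write_json(
    list(planted_target_genes = ds$truth$planted_target_genes,
         planted_repeat_regions = ds$truth$planted_repeat_regions,
         planted_repeat_counts = as.list(ds$truth$planted_repeat_counts)),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}

#' Read a synthetic dataset directory back into a bundle
#'
#' Inverse of [write_synth_dataset()]; the returned bundle feeds
#' [run_discovery()] and [run_stratification()] directly.
#'
#' @param dir dataset directory.
#' @return A `synth_dataset`-shaped list (without the generator config).
#' @export
read_synth_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  genome <- as.character(Biostrings::readDNAStringSet(p("genome.fa")))
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- read.delim(p("annotation.tsv"), stringsAsFactors = FALSE)
  names(ann)[names(ann) == "tss_0based"] <- "tss"
  cohort_files <- c("kd", "lines", "tumors", "met", "normals")
  cohorts <- lapply(setNames(cohort_files, cohort_files), function(nm) {
    f <- p(paste0(nm, ".tsv"))
    if (file.exists(f)) load_expression(f, p("labels.tsv")) else NULL
  })
  cohorts <- cohorts[!vapply(cohorts, is.null, logical(1))]
  pairs <- if (file.exists(p("kd_pairs.tsv")))
    read.delim(p("kd_pairs.tsv"), stringsAsFactors = FALSE) else NULL
  peaks <- list()
  for (cond in c("fusion_on", "fusion_off")) {
    f <- p(paste0("peaks_", cond, ".bed"))
    if (file.exists(f)) peaks[[cond]] <- read_bed(f)
  }
  tracks <- list()
  for (cond in c("fusion_on", "fusion_off")) {
    f <- p(paste0("coverage_", cond, ".bedGraph"))
    if (file.exists(f)) tracks[[cond]] <- read_bedgraph(f)
  }
  truth <- if (file.exists(p("ground_truth.json"))) {
    gt <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
    gt$planted_repeat_counts <- unlist(gt$planted_repeat_counts)
    gt
  } else NULL
  structure(list(genome = genome, annotation = ann, cohorts = cohorts,
                 pairs = pairs, peaks = peaks, tracks = tracks, truth = truth),
            class = "synth_dataset")
}
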