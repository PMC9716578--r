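#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic data generator. The defaults are the
#' desk-scale study conditions the package is validated under: ~1,000 genes of
#' which 30 are planted fusion targets, 3 paired knockdown/control cell lines,
#' 60 typed pan-cancer cell lines over 12 types (one of them the fusion-driven
#' target type), 120 typed tumors, 60 metastases of which 11 carry the fusion,
#' and 20 normal tissues.
#'
#' Expression is simulated directly on the log2-FPKM scale: every gene gets a
#' cohort-independent baseline mean, planted targets get a high target-type
#' mean, are knocked down by `kd_log2_effect` log2 units in the fusion
#' knockdown samples, and are below the detection floor (reported as 0 FPKM)
#' in every non-target sample.
#'
#' @param n_genes total number of genes.
#' @param n_planted_targets number of planted fusion-target genes
#'   (`< n_genes`).
#' @param n_kd_cell_lines number of knockdown/control cell-line pairs.
#' @param n_pancancer_lines number of pan-cancer cell lines (includes the
#'   target-type lines).
#' @param n_cancer_types number of cancer types across the cell-line cohort,
#'   including the target type.
#' @param n_tumor_samples number of primary tumors (non-target types only,
#'   mirroring a fusion-free pan-cancer tumor cohort).
#' @param n_met_samples number of metastasis samples.
#' @param n_met_ews number of fusion-positive (target-type) metastases
#'   (`< n_met_samples`).
#' @param n_normal_tissues number of normal tissue types.
#' @param samples_per_tissue normal samples per tissue type.
#' @param baseline_log2fpkm_mean,baseline_log2fpkm_sd log2-FPKM mean/sd of the
#'   per-gene baseline expression shared by all cohorts.
#' @param baseline_log2fpkm_min,planted_log2fpkm_min lower truncation of the
#'   per-gene baseline and planted target-type means: the generator emulates
#'   genes that are genuinely expressed in their cohorts (fully silent
#'   background genes are not simulated), so every background gene clears the
#'   expression gates off-target and every planted target clears them in the
#'   target type.
#' @param planted_log2fpkm_mean log2-FPKM mean of planted targets in
#'   target-type samples (per-gene means are drawn around it with
#'   `baseline_log2fpkm_sd` spread).
#' @param kd_log2_effect log2 fold reduction of planted targets under fusion
#'   knockdown; must be >= 1 so planted targets clear the >=2-fold filter in
#'   expectation.
#' @param noise_sd per-sample log2-FPKM jitter.
#' @param offtarget_log2fpkm_mean,offtarget_log2fpkm_sd truncated log-normal
#'   for planted-target expression outside the target type; defaults sit far
#'   below the detection floor, so off-target values are reported as 0 FPKM,
#'   the silent-gene pattern the generator emulates.
#' @param detection_floor_fpkm FPKM below which simulated expression is
#'   reported as 0.
#' @param genome_len_per_gene bp of genome allotted to each background gene.
#' @param planted_isolation_bp bp of gene-free genome on each side of a
#'   planted gene's TSS, so no other TSS falls inside the direct-target
#'   window.
#' @param genes_per_chrom genes per synthetic chromosome.
#' @param planted_repeat_len number of consecutive motif copies planted in
#'   each fusion-bound regulatory region (>= 5).
#' @param peak_window_offset_bp distance (bp) from each planted gene's TSS to
#'   its planted regulatory region; must be < 100000 so the region falls
#'   inside the +/-100 kb direct-target window.
#' @param peak_margin_bp bp of flanking sequence included in each planted
#'   peak interval around the repeat run.
#' @param n_decoy_peaks number of decoy peaks placed on a gene-free
#'   chromosome (> 100 kb from every TSS).
#' @param track_background,track_peak_gain per-bp coverage of the background
#'   and the additional per-bp coverage over active regulatory windows.
#' @param flank_signal_bp half-width of the elevated coverage window around
#'   active peaks.
#' @param seed RNG seed governing the whole generator.
#'
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 1000,
                         n_planted_targets = 30,
                         n_kd_cell_lines = 3,
                         n_pancancer_lines = 60,
                         n_cancer_types = 12,
                         n_tumor_samples = 120,
                         n_met_samples = 60,
                         n_met_ews = 11,
                         n_normal_tissues = 20,
                         samples_per_tissue = 3,
                         baseline_log2fpkm_mean = 3,
                         baseline_log2fpkm_sd = 1.5,
                         baseline_log2fpkm_min = 1,
                         planted_log2fpkm_mean = 5,
                         planted_log2fpkm_min = 3,
                         kd_log2_effect = 4,
                         noise_sd = 0.4,
                         offtarget_log2fpkm_mean = -12,
                         offtarget_log2fpkm_sd = 0.8,
                         detection_floor_fpkm = 0.01,
                         genome_len_per_gene = 2000,
                         planted_isolation_bp = 150000,
                         genes_per_chrom = 50,
                         planted_repeat_len = 9,
                         peak_window_offset_bp = 5000,
                         peak_margin_bp = 150,
                         n_decoy_peaks = 15,
                         track_background = 1,
                         track_peak_gain = 20,
                         flank_signal_bp = 2500,
                         seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg a `synth_config` object (or plain list of its fields).
#' @export
validate_synth_config <- function(cfg) {
  counts <- c("n_genes", "n_planted_targets", "n_kd_cell_lines",
              "n_pancancer_lines", "n_cancer_types", "n_tumor_samples",
              "n_met_samples", "n_met_ews", "n_normal_tissues",
              "samples_per_tissue", "genes_per_chrom", "planted_repeat_len")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v))
      stop(sprintf("synth_config: '%s' must be a single integer >= 1", f))
  }
  if (cfg$n_planted_targets >= cfg$n_genes)
    stop("synth_config: n_planted_targets must be < n_genes")
  if (cfg$n_met_ews >= cfg$n_met_samples)
    stop("synth_config: n_met_ews must be < n_met_samples")
  if (cfg$n_cancer_types < 2)
    stop("synth_config: n_cancer_types must be >= 2")
  if (cfg$kd_log2_effect < 1)
    stop("synth_config: kd_log2_effect must be >= 1 (guarantees the >=2-fold filter in expectation)")
  if (cfg$planted_repeat_len < 5)
    stop("synth_config: planted_repeat_len must be >= 5")
  if (cfg$peak_window_offset_bp >= 100000)
    stop("synth_config: peak_window_offset_bp must be < 100000")
  if (cfg$peak_window_offset_bp <= 4 * cfg$planted_repeat_len + cfg$peak_margin_bp)
    stop("synth_config: peak_window_offset_bp too small for the planted repeat and peak margin")
  if (cfg$planted_isolation_bp <= cfg$peak_window_offset_bp + 100000)
    stop("synth_config: planted_isolation_bp must exceed peak_window_offset_bp + 100000 to isolate planted loci")
  if (cfg$noise_sd <= 0 || cfg$baseline_log2fpkm_sd <= 0)
    stop("synth_config: noise_sd and baseline_log2fpkm_sd must be > 0")
  if (cfg$detection_floor_fpkm < 0)
    stop("synth_config: detection_floor_fpkm must be >= 0")
  if (cfg$track_background <= 0 || cfg$track_peak_gain <= 0)
    stop("synth_config: track values must be > 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("synth_config: seed must be a single number")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic study configuration\n")
  cat(sprintf("  genes: %d (%d planted targets), seed %s\n",
              x$n_genes, x$n_planted_targets, format(x$seed)))
  cat(sprintf("  cohorts: %d KD pairs | %d lines/%d types | %d tumors | %d mets (%d target) | %d tissues\n",
              x$n_kd_cell_lines, x$n_pancancer_lines, x$n_cancer_types,
              x$n_tumor_samples, x$n_met_samples, x$n_met_ews,
              x$n_normal_tissues))
  invisible(x)
}

# Planted-gene indices are the first draw of the generator RNG stream so that
# every generator component (genome, cohorts, peaks) agrees on them.
.planted_idx <- function(cfg) {
  set.seed(.sub_seed(cfg$seed, 0L))
  sort(sample.int(cfg$n_genes, cfg$n_planted_targets))
}

.gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

.target_type <- "EwS"

.type_labels <- function(cfg) {
  c(.target_type, sprintf("C%02d", seq_len(cfg$n_cancer_types - 1L)))
}
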