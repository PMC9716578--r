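# Shared fixtures, built in code. Desk-scale configuration for unit tests;
# the acceptance tests use the generator defaults.

small_cfg <- function(seed = 1, ...) {
  synth_config(n_genes = 120, n_planted_targets = 6, n_kd_cell_lines = 3,
               n_pancancer_lines = 24, n_cancer_types = 6,
               n_tumor_samples = 24, n_met_samples = 20, n_met_ews = 5,
               n_normal_tissues = 6, samples_per_tissue = 2,
               n_decoy_peaks = 6, seed = seed, ...)
}

# lazily built, memoized datasets (one generator run shared across files)
.fixtures <- new.env(parent = emptyenv())

small_dataset <- function(seed = 1) {
  key <- paste0("small_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_synth_dataset(small_cfg(seed = seed))
  .fixtures[[key]]
}

default_dataset <- function(seed = 1) {
  key <- paste0("default_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_synth_dataset(synth_config(seed = seed))
  .fixtures[[key]]
}

# small labelled expression matrix from a plain values matrix
toy_expr <- function(values, type_label, cohort = "toy") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, data.frame(
    sample_id = colnames(values), cohort = cohort, type_label = type_label,
    stringsAsFactors = FALSE))
}

# expression matrix whose log2(FPKM + 1) equals a given matrix exactly
expr_from_log2 <- function(log2mat, type_label, cohort = "toy") {
  toy_expr(2^log2mat - 1, type_label, cohort)
}

strip_timestamp <- function(path) {
  lines <- readLines(path)
  lines[!grepl("\"timestamp\"", lines)]
}

md5_of <- function(paths) unname(tools::md5sum(paths))
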