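#' Generate the synthetic multi-cohort expression matrices
#'
#' Emits five labelled FPKM cohorts sharing one gene universe:
#' \describe{
#'   \item{kd}{paired shControl/shFusion samples for each knockdown cell
#'     line (all target-type).}
#'   \item{lines}{typed pan-cancer cell lines, including target-type lines.}
#'   \item{tumors}{typed pan-cancer primary tumors (no target type,
#'     mirroring a fusion-free tumor cohort).}
#'   \item{met}{typed metastases containing `n_met_ews` target-type samples.}
#'   \item{normals}{typed normal tissues.}
#' }
#'
#' Background genes share a cohort-independent log-normal baseline with
#' `noise_sd` jitter. Planted targets are drawn log-normally around
#' `planted_log2fpkm_mean` in target-type samples, knocked down by
#' `2^kd_log2_effect` in shFusion samples, and drawn from a truncated
#' log-normal below the detection floor (hence reported as 0 FPKM) in every
#' non-target sample.
#'
#' @param cfg a [synth_config()].
#' @return A list with `cohorts` (named list of `SummarizedExperiment`s),
#'   `pairs` (data.frame of shControl/shFusion sample ids per cell line) and
#'   `truth` (the planted gene ids).
.rtrunc_norm <- function(n, mu, sd, lower) {
  lo <- pnorm(lower, mu, sd)
  qnorm(lo + runif(n) * (1 - lo), mu, sd)
}

#' @export
make_cohorts <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  planted <- .planted_idx(cfg)
  ids <- .gene_ids(cfg)
  types <- .type_labels(cfg)
  nonews <- types[types != .target_type]

  set.seed(.sub_seed(cfg$seed, 2L))
  mu_bg <- .rtrunc_norm(cfg$n_genes, cfg$baseline_log2fpkm_mean,
                        cfg$baseline_log2fpkm_sd, cfg$baseline_log2fpkm_min)
  mu_pl <- .rtrunc_norm(length(planted), cfg$planted_log2fpkm_mean,
                        cfg$baseline_log2fpkm_sd, cfg$planted_log2fpkm_min)

  block <- function(sample_ids, type_label, cohort, kd_cols = logical(length(sample_ids))) {
    n_s <- length(sample_ids)
    x <- matrix(rnorm(cfg$n_genes * n_s, 0, cfg$noise_sd), cfg$n_genes, n_s) + mu_bg
    is_tt <- type_label == .target_type
    for (k in seq_along(planted)) {
      g <- planted[k]
      x[g, is_tt] <- mu_pl[k] + rnorm(sum(is_tt), 0, cfg$noise_sd)
      x[g, is_tt & kd_cols] <- x[g, is_tt & kd_cols] - cfg$kd_log2_effect
    }
    f <- 2^x
    if (any(!is_tt)) {
      off <- matrix(
        2^rnorm(length(planted) * sum(!is_tt), cfg$offtarget_log2fpkm_mean,
                cfg$offtarget_log2fpkm_sd),
        length(planted), sum(!is_tt))
      off[off < cfg$detection_floor_fpkm] <- 0
      f[planted, !is_tt] <- off
    }
    f <- round(f, 4)
    dimnames(f) <- list(ids, sample_ids)
    labels <- data.frame(sample_id = sample_ids, cohort = cohort,
                         type_label = type_label, stringsAsFactors = FALSE)
    expression_matrix(f, labels)
  }

  # paired knockdown/control cell lines
  cl <- sprintf("CL%d", seq_len(cfg$n_kd_cell_lines))
  kd_ids <- as.vector(rbind(sprintf("kd_%s_shControl", cl),
                            sprintf("kd_%s_shFusion", cl)))
  kd <- block(kd_ids, rep(.target_type, length(kd_ids)), "kd",
              kd_cols = grepl("shFusion$", kd_ids))
  pairs <- data.frame(ctrl = sprintf("kd_%s_shControl", cl),
                      kd = sprintf("kd_%s_shFusion", cl),
                      stringsAsFactors = FALSE)

  # typed pan-cancer cell lines (round-robin over all types, target included)
  line_types <- types[(seq_len(cfg$n_pancancer_lines) - 1L) %% length(types) + 1L]
  lines <- block(sprintf("line%03d", seq_len(cfg$n_pancancer_lines)),
                 line_types, "lines")

  tumor_types <- nonews[(seq_len(cfg$n_tumor_samples) - 1L) %% length(nonews) + 1L]
  tumors <- block(sprintf("tumor%03d", seq_len(cfg$n_tumor_samples)),
                  tumor_types, "tumors")

  met_types <- c(rep(.target_type, cfg$n_met_ews),
                 nonews[(seq_len(cfg$n_met_samples - cfg$n_met_ews) - 1L) %% length(nonews) + 1L])
  met <- block(sprintf("met%03d", seq_len(cfg$n_met_samples)), met_types, "met")

  tissues <- sprintf("T%02d", seq_len(cfg$n_normal_tissues))
  norm_types <- rep(tissues, each = cfg$samples_per_tissue)
  normals <- block(sprintf("norm_%s_%d", norm_types,
                           rep(seq_len(cfg$samples_per_tissue), cfg$n_normal_tissues)),
                   norm_types, "normals")

  list(cohorts = list(kd = kd, lines = lines, tumors = tumors, met = met,
                      normals = normals),
       pairs = pairs,
       truth = list(planted_target_genes = ids[planted]))
}
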