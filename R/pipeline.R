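#' Pipeline configuration
#'
#' Collects every threshold of the discovery cascade and the stratification
#' analyses, with the published defaults: expression gate 1 FPKM, fold gate
#' 2, direct-target window 100 kb, microsatellite threshold 5 copies,
#' network threshold r >= 0.5, enrichment calls at NES > 1.5 and q < 0.05.
#' Unknown keys are rejected.
#'
#' @param input_dir directory holding the dataset (layout of
#'   [write_synth_dataset()]); may be `NULL` when an in-memory bundle is
#'   passed to the runners.
#' @param output_dir optional directory for reports and tables.
#' @param overwrite allow writing into an output directory produced by a
#'   different configuration.
#' @param target_type the fusion-driven type label.
#' @param direction,min_expr,min_fold,pseudocount see [common_regulated()].
#' @param line_max_fpkm see [specificity_filter_lines()].
#' @param window_bp see [assign_peaks_to_tss()].
#' @param motif,min_repeats,repeat_flank_bp see [annotate_repeats()].
#' @param type_fpkm_thr,max_other_types,type_stat see
#'   [specificity_filter_types()].
#' @param tissue_fpkm_thr,max_tissues see [tissue_screen()].
#' @param apply_tissue_filter drop tissue-flagged genes from the final list
#'   (default `TRUE`).
#' @param peaks_condition which peak set drives direct-target calling
#'   (default `"fusion_on"`).
#' @param r_min,nes_min,q_max,n_perm see [build_network()] and
#'   [stratify_cohort()].
#' @param signature_file optional TSV (first column gene ids) supplying the
#'   stratification signature.
#' @param seed seed for all stochastic steps.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            output_dir = NULL,
                            overwrite = FALSE,
                            target_type = "EwS",
                            direction = "down",
                            min_expr = 1,
                            min_fold = 2,
                            pseudocount = 0.01,
                            line_max_fpkm = 1,
                            window_bp = 100000,
                            motif = "GGAA",
                            min_repeats = 5,
                            repeat_flank_bp = 0,
                            type_fpkm_thr = 1,
                            max_other_types = 1,
                            type_stat = "median",
                            tissue_fpkm_thr = 1,
                            max_tissues = 1,
                            apply_tissue_filter = TRUE,
                            peaks_condition = "fusion_on",
                            r_min = 0.5,
                            nes_min = 1.5,
                            q_max = 0.05,
                            n_perm = 1000,
                            signature_file = NULL,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_fold >= 1, cfg$window_bp > 0, cfg$min_repeats >= 1,
            cfg$r_min >= -1, cfg$r_min <= 1,
            cfg$q_max > 0, cfg$q_max <= 1, cfg$n_perm >= 100,
            cfg$direction %in% c("down", "up"),
            cfg$type_stat %in% c("median", "mean", "any"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# md5 of the canonical JSON form of a config; recorded in every report so
# partial outputs from a different configuration are refused.
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  # hash the analysis parameters, not where the run reads or writes
  cfg <- cfg[setdiff(names(cfg), c("input_dir", "output_dir", "overwrite"))]
  js <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                         null = "null", digits = NA)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(md5sum(tmp))
}

.check_outdir <- function(cfg, report_file) {
  if (is.null(cfg$output_dir)) return(invisible(NULL))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cfg$output_dir, report_file)
  if (file.exists(f) && !isTRUE(cfg$overwrite)) {
    old <- try(jsonlite::read_json(f), silent = TRUE)
    if (!inherits(old, "try-error") && !is.null(old$config_hash) &&
        old$config_hash != .config_hash(cfg))
      stop("output_dir holds results from a different configuration; ",
           "set overwrite = TRUE to replace them")
  }
  invisible(NULL)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) .stop_ctx(name, e))
}

#' Run the full discovery cascade
#'
#' Executes, in order: knockdown intersection ([common_regulated()]),
#' cell-line specificity ([specificity_filter_lines()]), direct-target
#' calling ([assign_peaks_to_tss()] + [direct_targets()]), microsatellite
#' annotation of the assigned peaks ([annotate_repeats()]), tumor- and
#' metastasis-cohort type specificity ([specificity_filter_types()], applied
#' to each cohort and intersected), and the normal-tissue screen
#' ([tissue_screen()]). Stage order follows the discovery flowchart:
#' expression filters before ChIP integration before type specificity, since
#' each filter acts on the survivors of the previous one. Any stage error
#' aborts the run with the stage name (fail-fast).
#'
#' @param config a [pipeline_config()].
#' @param data optional in-memory `synth_dataset` bundle; when `NULL` the
#'   dataset is read from `config$input_dir`.
#' @return A `discovery_report`: per-stage counts and gene lists, repeat
#'   summary, tissue report, final candidate list and run metadata.
#' @export
run_discovery <- function(config, data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(data)) {
    if (is.null(config$input_dir)) stop("either data or config$input_dir is required")
    data <- .stage("load", read_synth_dataset(config$input_dir))
  }
  .check_outdir(config, "discovery_report.json")

  stages <- list()
  note <- function(stage, gs, n_in) {
    message(sprintf("[discovery:%s] in=%d out=%d", stage, n_in, length(gs$genes)))
    stages[[stage]] <<- list(n_in = n_in, n_out = length(gs$genes), genes = gs$genes)
  }

  n_genes <- nrow(fpkm(data$cohorts$kd))
  common <- .stage("common_regulated",
                   common_regulated(data$cohorts$kd, data$pairs,
                                    direction = config$direction,
                                    min_expr = config$min_expr,
                                    min_fold = config$min_fold,
                                    pseudocount = config$pseudocount))
  note("common_regulated", common, n_genes)

  lines_gs <- .stage("specificity_lines",
                     specificity_filter_lines(common, data$cohorts$lines,
                                              config$target_type,
                                              max_fpkm = config$line_max_fpkm))
  note("specificity_lines", lines_gs, length(common$genes))

  peaks <- data$peaks[[config$peaks_condition]]
  if (is.null(peaks)) stop("peak condition '", config$peaks_condition, "' not in dataset")
  chrom_sizes <- setNames(nchar(data$genome), names(data$genome))
  assignment <- .stage("assign_peaks",
                       assign_peaks_to_tss(peaks, data$annotation,
                                           window_bp = config$window_bp,
                                           chrom_sizes = chrom_sizes))
  direct <- .stage("direct_targets", direct_targets(lines_gs, assignment))
  note("direct_targets", direct, length(lines_gs$genes))

  target_peak_names <- unique(unlist(assignment[direct$genes]))
  target_peaks <- peaks[peaks$name %in% target_peak_names, , drop = FALSE]
  repeats <- if (nrow(target_peaks)) {
    .stage("annotate_repeats",
           annotate_repeats(target_peaks, data$genome, motif = config$motif,
                            min_repeats = config$min_repeats,
                            flank_bp = config$repeat_flank_bp))
  } else NULL
  message(sprintf("[discovery:annotate_repeats] regions=%d fraction_ge_%d=%.3f",
                  if (is.null(repeats)) 0L else nrow(repeats$regions),
                  config$min_repeats,
                  if (is.null(repeats)) NA_real_ else repeats$fraction_ge_threshold))

  types_gs <- direct
  for (nm in intersect(c("tumors", "met"), names(data$cohorts))) {
    step <- .stage(paste0("specificity_types_", nm),
                   specificity_filter_types(types_gs, data$cohorts[[nm]],
                                            target_type = config$target_type,
                                            fpkm_thr = config$type_fpkm_thr,
                                            max_other_types = config$max_other_types,
                                            type_stat = config$type_stat))
    note(paste0("specificity_types_", nm), step, length(types_gs$genes))
    types_gs <- step
  }

  screen <- .stage("tissue_screen",
                   tissue_screen(types_gs, data$cohorts$normals,
                                 fpkm_thr = config$tissue_fpkm_thr,
                                 max_tissues = config$max_tissues,
                                 type_stat = config$type_stat))
  final_genes <- if (isTRUE(config$apply_tissue_filter)) {
    setdiff(types_gs$genes, screen$report$gene_id[screen$report$flagged])
  } else types_gs$genes
  final <- .append_prov(screen$genes, final_genes, "final")
  note("final", final, length(types_gs$genes))

  counts <- vapply(stages, `[[`, numeric(1), "n_out")
  if (any(diff(counts) > 0))
    stop("internal error: cascade gene counts increased between stages")

  report <- structure(list(
    stages = data.frame(stage = names(stages),
                        n_in = vapply(stages, `[[`, numeric(1), "n_in"),
                        n_out = counts, row.names = NULL,
                        stringsAsFactors = FALSE),
    gene_lists = lapply(stages, `[[`, "genes"),
    repeat_fraction = if (is.null(repeats)) NA_real_ else repeats$fraction_ge_threshold,
    repeat_annotation = repeats,
    tissue_report = screen$report,
    final_candidates = final,
    config_hash = .config_hash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "discovery_report")

  if (!is.null(config$output_dir)) .write_discovery_report(report, config)
  report
}

.write_discovery_report <- function(report, config) {
  out <- config$output_dir
  for (nm in names(report$gene_lists)) {
    write.table(data.frame(gene_id = report$gene_lists[[nm]]),
                file.path(out, paste0("genes_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$repeat_annotation))
    write_repeat_annotation(report$repeat_annotation,
                            file.path(out, "repeat_annotation.tsv"))
  write.table(report$tissue_report, file.path(out, "tissue_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_set(report$final_candidates, file.path(out, "final_candidates.tsv"))
  jsonlite::write_json(
    list(stages = report$stages,
         repeat_fraction = report$repeat_fraction,
         final_candidates = report$final_candidates$genes,
         provenance = report$final_candidates$provenance,
         config_hash = report$config_hash,
         seed = report$seed,
         timestamp = report$timestamp),
    file.path(out, "discovery_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("discovery_report\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-24s %4d -> %4d\n", x$stages$stage[i],
                x$stages$n_in[i], x$stages$n_out[i]))
  cat(sprintf("  repeat fraction >= threshold: %.3f\n", x$repeat_fraction))
  cat(sprintf("  final candidates: %d\n", length(x$final_candidates$genes)))
  invisible(x)
}

#' Run the signature stratification analyses
#'
#' Builds the sample-sample correlation network over the signature
#' ([correlation_matrix()], [build_network()], [component_stats()]), calls
#' per-sample signature enrichment ([stratify_cohort()]) and computes the
#' per-gene specificity heatmap ([specificity_heatmap()]) on the metastasis
#' cohort.
#'
#' @inheritParams run_discovery
#' @param signature a [gene_set()] or character vector; when `NULL`,
#'   `config$signature_file` is read (first column = gene ids).
#' @return A `stratification_report` list with the network, component
#'   summary, per-sample calls and specificity matrices.
#' @export
run_stratification <- function(config, data = NULL, signature = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(data)) {
    if (is.null(config$input_dir)) stop("either data or config$input_dir is required")
    data <- .stage("load", read_synth_dataset(config$input_dir))
  }
  if (is.null(signature)) {
    if (is.null(config$signature_file))
      stop("a signature is required: pass `signature` or set config$signature_file")
    signature <- read.delim(config$signature_file, stringsAsFactors = FALSE)[[1]]
  }
  signature <- .as_gene_set(signature)
  if (length(signature$genes) < 2)
    stop("stratification requires a signature of >= 2 genes")
  .check_outdir(config, "stratification_report.json")
  met <- data$cohorts$met

  cm <- .stage("correlation", correlation_matrix(met, signature))
  g <- .stage("network", build_network(cm, sample_labels(met), r_min = config$r_min))
  comp <- .stage("components", component_stats(g, config$target_type))
  message(sprintf("[stratify:network] nodes=%d edges=%d largest_target_component=%d cross_edges=%d",
                  igraph::vcount(g), igraph::ecount(g),
                  comp$largest_target_component, comp$cross_label_edges))

  calls <- .stage("enrichment",
                  stratify_cohort(met, signature, nes_min = config$nes_min,
                                  q_max = config$q_max, n_perm = config$n_perm,
                                  seed = config$seed))
  message(sprintf("[stratify:enrichment] positive=%d/%d",
                  sum(calls$call), nrow(calls)))

  heat <- .stage("specificity",
                 specificity_heatmap(met, config$target_type, signature))

  report <- structure(list(
    network = g,
    components = comp,
    calls = calls,
    specificity = heat,
    signature = signature$genes,
    config_hash = .config_hash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "stratification_report")

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    write_network(g, file.path(out, "network.graphml"))
    write.table(calls, file.path(out, "stratification_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_specificity(heat, file.path(out, "specificity_neglog10p.tsv"))
    jsonlite::write_json(
      list(components = report$components,
           n_positive = sum(calls$call),
           n_samples = nrow(calls),
           signature = report$signature,
           config_hash = report$config_hash,
           seed = report$seed,
           timestamp = report$timestamp),
      file.path(out, "stratification_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("stratification_report\n")
  cat(sprintf("  signature: %d genes; samples: %d (%d called positive)\n",
              length(x$signature), nrow(x$calls), sum(x$calls$call)))
  cat(sprintf("  largest target component: %d; cross-label edges: %d\n",
              x$components$largest_target_component,
              x$components$cross_label_edges))
  invisible(x)
}
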