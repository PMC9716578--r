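#' Rank the genes of one sample against the cohort
#'
#' The per-sample ranking metric is the cross-sample z-score of
#' `log2(FPKM + 1)`: `z_g = (x_gs - mean_g) / sd_g` with moments taken across
#' all samples of the matrix. Genes with zero cross-sample variance get
#' `z = 0`. Ties are broken by gene id (lexicographic) for determinism.
#'
#' @param expr expression matrix with >= 3 samples.
#' @param sample_id the sample to rank.
#' @param metric `"zscore"` (default) or `"log2fpkm"` (raw log expression,
#'   exposed for sensitivity analysis).
#' @return data.frame `gene_id`, `score`, sorted by decreasing score.
#' @export
rank_sample <- function(expr, sample_id, metric = c("zscore", "log2fpkm")) {
  metric <- match.arg(metric)
  m <- log2(fpkm(expr) + 1)
  if (ncol(m) < 3) stop("ranking needs at least 3 samples for cross-sample moments")
  if (!sample_id %in% colnames(m)) stop("unknown sample: ", sample_id)
  if (metric == "zscore") {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, sd)
    z <- (m[, sample_id] - mu) / sdv
    z[sdv == 0] <- 0
  } else {
    z <- m[, sample_id]
  }
  ord <- order(-z, rownames(m))
  data.frame(gene_id = rownames(m)[ord], score = unname(z[ord]),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom: set members ("hits") increment the
#' running sum by `|score|^weight_p` normalized by the total hit weight;
#' non-members decrement it by `1/(N - n_set)`. The enrichment score is the
#' running-sum value of maximal absolute deviation from zero (signed).
#'
#' @param ranked data.frame from [rank_sample()] (or any `gene_id`/`score`
#'   table sorted by decreasing score), or a named numeric vector of scores.
#' @param set gene ids of the query set; the intersection with the ranking
#'   must be non-empty.
#' @param weight_p score-weighting exponent (default 1).
#' @return list with `ES` (in `[-1, 1]`) and `running_score` (profile over
#'   all N ranks).
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  rs <- .ranked_scores(ranked)
  hit <- names(rs) %in% as.character(.as_gene_set(set)$genes)
  if (!any(hit)) stop("gene set has empty intersection with the ranked list")
  if (all(hit)) stop("gene set covers the whole ranked list")
  w <- abs(rs)^weight_p
  wh <- w * hit
  tot <- sum(wh)
  p_hit <- if (tot > 0) cumsum(wh) / tot else cumsum(hit) / sum(hit)
  p_miss <- cumsum(!hit) / sum(!hit)
  dev <- p_hit - p_miss
  es <- dev[which.max(abs(dev))]
  list(ES = unname(es), running_score = unname(dev))
}

.ranked_scores <- function(ranked) {
  if (is.data.frame(ranked)) {
    rs <- setNames(ranked$score, ranked$gene_id)
  } else {
    rs <- ranked
  }
  if (is.null(names(rs))) stop("ranked scores must carry gene ids")
  if (is.unsorted(rev(rs))) {
    # tolerate unsorted input: sort by decreasing score, gene id tiebreak
    rs <- rs[order(-rs, names(rs))]
  }
  rs
}

# O(n_set) enrichment score used inside the permutation loop: the running
# sum attains its extrema just before or just after a hit, so only those 2n
# candidate values are evaluated. Verified equal to enrichment_score() in the
# test suite.
.es_fast <- function(w_all, hit_pos, n_total, tot_w = NULL) {
  hit_pos <- sort.int(hit_pos)
  n <- length(hit_pos)
  wh <- w_all[hit_pos]
  tot <- if (is.null(tot_w)) sum(wh) else tot_w
  cw <- if (tot > 0) cumsum(wh) / tot else seq_len(n) / n
  miss_step <- 1 / (n_total - n)
  i <- seq_len(n)
  after <- cw - (hit_pos - i) * miss_step
  before <- c(0, cw[-n]) - (hit_pos - i) * miss_step
  cand <- as.vector(rbind(before, after))
  cand[which.max(abs(cand))]
}

#' Permutation-normalized enrichment of a gene set in a ranking
#'
#' Builds the null by re-drawing random gene sets of the same size from the
#' ranked list (`n_perm` times), then normalizes: `NES = ES / mean(|null ES|)`
#' over the same-sign null, and `p_perm = (1 + k) / (1 + m)` where `m` counts
#' same-sign null scores and `k` those at least as extreme as the observed
#' ES. A gene-set permutation null is used because per-sample calls admit no
#' phenotype permutation.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed; fixed seed implies identical results.
#' @return An `enrichment_result`: list with `ES`, `NES`, `p_perm`,
#'   `n_perm`, `size`, and `running_score`.
#' @export
nes_permutation <- function(ranked, set, n_perm = 1000, seed = 1, weight_p = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  rs <- .ranked_scores(ranked)
  if (all(rs == 0)) stop("degenerate ranking: all metrics are zero")
  obs <- enrichment_score(rs, set, weight_p)
  n_total <- length(rs)
  hit <- which(names(rs) %in% as.character(.as_gene_set(set)$genes))
  n <- length(hit)
  w <- abs(rs)^weight_p
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    .es_fast(w, sample.int(n_total, n), n_total)
  }, numeric(1))
  es <- obs$ES
  if (es == 0) {
    nes <- 0; p <- 1
  } else {
    same <- null_es[sign(null_es) == sign(es)]
    denom <- mean(abs(same))
    nes <- if (length(same) && denom > 0) es / denom else 0
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }
  structure(list(ES = es, NES = nes, p_perm = p, n_perm = n_perm, size = n,
                 running_score = obs$running_score),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: ES %.3f, NES %.3f, p_perm %.4g (%d perms, set size %d)\n",
              x$ES, x$NES, x$p_perm, x$n_perm, x$size))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment (a thin, validated wrapper
#' around [stats::p.adjust]).
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Stratify a cohort by per-sample signature enrichment
#'
#' For every sample: rank the genes ([rank_sample()]), score the signature
#' ([enrichment_score()]) and normalize against a gene-set permutation null
#' ([nes_permutation()]); then adjust the permutation p-values across samples
#' by Benjamini-Hochberg. A sample is called signature-positive when
#' `NES > nes_min` and `q < q_max`.
#'
#' @param expr expression matrix of the cohort (>= 10 samples).
#' @param signature a [gene_set()] or character vector; must intersect the
#'   matrix genes.
#' @param nes_min NES call threshold (default 1.5, strict `>`).
#' @param q_max BH-adjusted p-value call threshold (default 0.05, strict
#'   `<`).
#' @param n_perm permutations per sample (default 1000).
#' @param seed master seed; per-sample permutation seeds are spawned from it
#'   deterministically.
#' @param metric ranking metric, see [rank_sample()].
#' @return data.frame with one row per sample: `sample_id`, `cohort`,
#'   `type_label`, `ES`, `NES`, `p_perm`, `q`, `call`.
#' @export
stratify_cohort <- function(expr, signature, nes_min = 1.5, q_max = 0.05,
                            n_perm = 1000, seed = 1,
                            metric = c("zscore", "log2fpkm")) {
  metric <- match.arg(metric)
  lab <- sample_labels(expr)
  if (nrow(lab) < 10) stop("cohort stratification needs >= 10 samples")
  genes <- intersect(as.character(.as_gene_set(signature)$genes),
                     rownames(fpkm(expr)))
  if (!length(genes)) stop("signature absent from the expression matrix")
  set.seed(.sub_seed(seed, 0L))
  sample_seeds <- sample.int(2147483646L, nrow(lab))
  res <- lapply(seq_len(nrow(lab)), function(i) {
    ranked <- rank_sample(expr, lab$sample_id[i], metric)
    nes_permutation(ranked, genes, n_perm = n_perm, seed = sample_seeds[i])
  })
  out <- data.frame(
    sample_id = lab$sample_id, cohort = lab$cohort,
    type_label = lab$type_label,
    ES = vapply(res, `[[`, numeric(1), "ES"),
    NES = vapply(res, `[[`, numeric(1), "NES"),
    p_perm = vapply(res, `[[`, numeric(1), "p_perm"),
    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p_perm)
  out$call <- out$NES > nes_min & out$q < q_max
  out
}

#' Enrichment of gene sets in an externally supplied pre-ranked list
#'
#' Accepts a `gene`/`metric` table (e.g. a differential-expression ranking)
#' and scores one or more gene sets against it with the permutation NES.
#'
#' @param ranking data.frame whose first two columns are gene id and ranking
#'   metric, or a path to such a TSV.
#' @param gene_sets named list of gene-id vectors.
#' @inheritParams stratify_cohort
#' @return data.frame with one row per gene set: `set`, `size`, `ES`, `NES`,
#'   `p_perm`, `q`.
#' @export
preranked_gsea <- function(ranking, gene_sets, n_perm = 1000, seed = 1) {
  if (is.character(ranking) && length(ranking) == 1)
    ranking <- read.delim(ranking, stringsAsFactors = FALSE)
  rs <- setNames(as.numeric(ranking[[2]]), as.character(ranking[[1]]))
  rs <- rs[order(-rs, names(rs))]
  set.seed(.sub_seed(seed, 0L))
  seeds <- sample.int(2147483646L, length(gene_sets))
  rows <- lapply(seq_along(gene_sets), function(i) {
    r <- nes_permutation(rs, gene_sets[[i]], n_perm = n_perm, seed = seeds[i])
    data.frame(set = names(gene_sets)[i], size = r$size, ES = r$ES,
               NES = r$NES, p_perm = r$p_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p_perm)
  out
}
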