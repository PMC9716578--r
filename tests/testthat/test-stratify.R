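test_that("correlation matrix matches the closed-form Pearson oracle", {
  set.seed(21)
  log2m <- matrix(runif(5 * 4, 0, 8), 5, 4,
                  dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  expr <- expr_from_log2(log2m, rep("t", 4))
  cm <- correlation_matrix(expr, gene_set(rownames(log2m)))
  for (i in 1:4) for (j in 1:4) {
    want <- if (i == j) 1 else oracle_pearson(log2m[, i], log2m[, j])
    expect_lt(abs(cm$r[i, j] - want), 1e-10)
  }
  # random larger instance
  log2b <- matrix(runif(30 * 8, 0, 8), 30, 8,
                  dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  cmb <- correlation_matrix(expr_from_log2(log2b, rep("t", 8)),
                            gene_set(rownames(log2b)))
  for (i in 1:8) for (j in 1:8) {
    want <- if (i == j) 1 else oracle_pearson(log2b[, i], log2b[, j])
    expect_lt(abs(cmb$r[i, j] - want), 1e-10)
  }
})

test_that("correlation handles duplicates, anticorrelation and constants", {
  a <- c(1, 2, 3, 4, 5)
  log2m <- cbind(s1 = a, s2 = a, s3 = 6 - a, s4 = rep(2, 5))
  rownames(log2m) <- sprintf("g%d", 1:5)
  expr <- expr_from_log2(log2m, rep("t", 4))
  cm <- correlation_matrix(expr, gene_set(rownames(log2m)))
  expect_equal(cm$r["s1", "s2"], 1)          # duplicated sample
  expect_equal(cm$r["s1", "s3"], -1)         # gene-wise negation around mean
  expect_identical(cm$constant_samples, "s4")
  expect_equal(cm$r["s4", "s1"], 0)          # flagged constant sample
  expect_equal(unname(diag(cm$r)), c(1, 1, 1, 0))
  expect_error(correlation_matrix(expr, gene_set("g1")), "two signature genes")
})

test_that("network thresholding keeps isolated nodes and edge weights", {
  set.seed(2)
  log2m <- matrix(runif(20 * 6, 0, 8), 20, 6,
                  dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
  expr <- expr_from_log2(log2m, rep(c("X", "Y"), 3))
  cm <- correlation_matrix(expr, gene_set(rownames(log2m)))
  labels <- sample_labels(expr)
  g_none <- build_network(cm, labels, r_min = 1.01)
  expect_equal(igraph::vcount(g_none), 6)
  expect_equal(igraph::ecount(g_none), 0)
  g_all <- build_network(cm, labels, r_min = -1)
  expect_equal(igraph::ecount(g_all), 15)   # complete graph on 6 nodes
  # edges hold the rounded correlation as weight
  g_mid <- build_network(cm, labels, r_min = 0.2)
  e <- igraph::as_data_frame(g_mid, what = "edges")
  for (k in seq_len(nrow(e)))
    expect_equal(e$weight[k], round(cm$r[e$from[k], e$to[k]], 6))
  expect_true(all(e$weight >= 0.2))
})

test_that("graphml round trip preserves nodes, edges, weights and labels", {
  ds <- small_dataset(1)
  cm <- correlation_matrix(ds$cohorts$met, ds$truth$planted_target_genes)
  g <- build_network(cm, sample_labels(ds$cohorts$met))
  f <- tempfile(fileext = ".graphml")
  write_network(g, f)
  g2 <- read_network(f)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  e1 <- igraph::as_data_frame(g, what = "edges")
  e2 <- igraph::as_data_frame(g2, what = "edges")
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(e2), key(e1))
  expect_identical(e2$weight[order(key(e2))], e1$weight[order(key(e1))])
  expect_identical(igraph::V(g2)$label[match(igraph::V(g)$name, igraph::V(g2)$name)],
                   igraph::V(g)$label)
  unlink(f)
})

test_that("component statistics agree with a breadth-first-search oracle", {
  # edgeless graph: every node its own component
  cm0 <- structure(list(r = diag(3), sample_ids = c("a", "b", "c"),
                        constant_samples = character(0)),
                   class = "correlation_matrix")
  dimnames(cm0$r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  lab0 <- data.frame(sample_id = c("a", "b", "c"), cohort = "x",
                     type_label = c("T", "T", "U"), stringsAsFactors = FALSE)
  g0 <- build_network(cm0, lab0, r_min = 0.5)
  expect_identical(component_stats(g0, "T")$largest_target_component, 1L)

  set.seed(13)
  for (rep in 1:20) {
    n <- 12
    ids <- sprintf("s%02d", 1:n)
    r <- matrix(runif(n * n, -1, 1), n, n, dimnames = list(ids, ids))
    r <- (r + t(r)) / 2; diag(r) <- 1
    cm <- structure(list(r = r, sample_ids = ids,
                         constant_samples = character(0)),
                    class = "correlation_matrix")
    lab <- data.frame(sample_id = ids, cohort = "x",
                      type_label = sample(c("T", "U"), n, TRUE),
                      stringsAsFactors = FALSE)
    g <- build_network(cm, lab, r_min = 0.3)
    stats <- component_stats(g, "T")
    edges <- igraph::as_data_frame(g, what = "edges")
    comp <- oracle_components(ids, edges)
    targets <- ids[lab$type_label == "T"]
    per_comp <- table(comp[targets])
    want_largest <- if (length(per_comp)) max(per_comp) else 0L
    expect_equal(stats$largest_target_component, as.integer(want_largest),
                 ignore_attr = TRUE)
    want_cross <- sum((lab$type_label[match(edges$from, ids)] == "T") !=
                        (lab$type_label[match(edges$to, ids)] == "T"))
    expect_identical(stats$cross_label_edges, as.integer(want_cross))
  }
})

test_that("per-sample ranking is the cross-sample z-score with stable ties", {
  log2m <- rbind(exclusive = c(6, 0, 0, 0),
                 constant  = c(2, 2, 2, 2),
                 mid       = c(3, 1, 2, 2))
  colnames(log2m) <- sprintf("s%d", 1:4)
  expr <- expr_from_log2(log2m, rep("t", 4))
  rk <- rank_sample(expr, "s1")
  expect_identical(rk$gene_id[1], "exclusive")
  expect_equal(rk$score[rk$gene_id == "constant"], 0)
  # hand-computed z-scores
  z_mid <- (3 - mean(log2m["mid", ])) / sd(log2m["mid", ])
  expect_equal(rk$score[rk$gene_id == "mid"], z_mid)
  expect_error(rank_sample(expr, "nope"), "unknown sample")
  # lexicographic tie-break among constant genes
  log2t <- rbind(b_gene = c(1, 1, 1), a_gene = c(1, 1, 1), z_gene = c(5, 1, 1))
  colnames(log2t) <- sprintf("s%d", 1:3)
  rkt <- rank_sample(expr_from_log2(log2t, rep("t", 3)), "s1")
  expect_identical(rkt$gene_id, c("z_gene", "a_gene", "b_gene"))
})

test_that("enrichment score equals the exhaustive running-sum oracle", {
  scores <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1),
                     sprintf("g%02d", 1:10))
  # set at ranks 1,4,7 of an N = 10 list
  set147 <- c("g01", "g04", "g07")
  got <- enrichment_score(scores, set147)
  expect_equal(got$ES, oracle_es(scores, set147))
  expect_identical(length(got$running_score), 10L)
  # top-k set with positive metrics peaks at exactly 1
  expect_equal(enrichment_score(scores, c("g01", "g02", "g03"))$ES, 1.0)
  # bottom-k set is strictly negative
  expect_lt(enrichment_score(scores, c("g09", "g10"))$ES, 0)
  expect_error(enrichment_score(scores, "absent"), "empty intersection")

  # randomized instances, including negative metrics
  set.seed(31)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    sc <- sort(rnorm(n), decreasing = TRUE)
    names(sc) <- sprintf("r%03d", seq_len(n))
    set <- sample(names(sc), sample(3:8, 1))
    es <- enrichment_score(sc, set)$ES
    expect_equal(es, oracle_es(sc, set))
    expect_gte(es, -1); expect_lte(es, 1)
    # fast path used by the permutation null agrees with the full scan
    fast <- fusiontarget:::.es_fast(abs(sc), which(names(sc) %in% set), n)
    expect_equal(fast, es)
  }
})

test_that("enrichment score matches the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  for (i in 1:25) {
    n <- 50
    sc <- sort(rnorm(n), decreasing = TRUE)
    names(sc) <- sprintf("r%03d", seq_len(n))
    idx <- sort(sample.int(n, 6))
    es <- enrichment_score(sc, names(sc)[idx])$ES
    ref <- fgsea::calcGseaStat(sc, idx, gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-12)
  }
})

test_that("permutation NES is deterministic and keeps the sign of ES", {
  set.seed(17)
  sc <- sort(rnorm(200), decreasing = TRUE)
  names(sc) <- sprintf("r%03d", 1:200)
  top_set <- names(sc)[1:12]
  r1 <- nes_permutation(sc, top_set, n_perm = 200, seed = 5)
  r2 <- nes_permutation(sc, top_set, n_perm = 200, seed = 5)
  expect_identical(r1, r2)
  expect_gt(r1$NES, 0)
  expect_identical(sign(r1$NES), sign(r1$ES))
  expect_gte(r1$p_perm, 1 / (r1$n_perm + 1))
  bottom <- names(sc)[189:200]
  rb <- nes_permutation(sc, bottom, n_perm = 200, seed = 5)
  expect_lt(rb$NES, 0)
  expect_error(nes_permutation(sc, top_set, n_perm = 50), "n_perm")
  expect_error(nes_permutation(setNames(rep(0, 200), names(sc)), top_set,
                               n_perm = 200), "degenerate")
})

test_that("NES is monotone in ES at a fixed null", {
  set.seed(23)
  sc <- sort(abs(rnorm(300)) + 0.1, decreasing = TRUE)
  names(sc) <- sprintf("r%03d", 1:300)
  res <- lapply(c(1, 40, 120), function(k)
    nes_permutation(sc, names(sc)[k:(k + 9)], n_perm = 300, seed = 9))
  es <- sapply(res, `[[`, "ES")
  nes <- sapply(res, `[[`, "NES")
  pos <- es > 0
  expect_identical(order(es[pos]), order(nes[pos]))
})

test_that("BH adjustment reproduces hand computations", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(25)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("specificity t-tests match the closed-form Welch formula", {
  x <- c(5.1, 4.8, 5.6); y <- c(1.2, 0.8, 1.9)
  log2m <- rbind(gene1 = c(x, y), gene2 = rep(2, 6))
  colnames(log2m) <- sprintf("s%d", 1:6)
  expr <- expr_from_log2(log2m, rep(c("EwS", "Other"), each = 3))
  sr <- specificity_heatmap(expr, "EwS", gene_set(c("gene1", "gene2")))
  want <- oracle_welch(x, y)
  expect_equal(sr$t["gene1", "Other"], want$t)
  expect_equal(sr$p["gene1", "Other"], want$p)
  expect_equal(sr$neglog10p["gene1", "Other"], -log10(want$p))
  # identical degenerate groups: t = 0, p = 1, cell = 0
  expect_equal(sr$t["gene2", "Other"], 0)
  expect_equal(sr$p["gene2", "Other"], 1)
  expect_equal(sr$neglog10p["gene2", "Other"], 0)
  # planted target vs any non-target type on synthetic data: cell > 2
  ds <- small_dataset(1)
  srm <- specificity_heatmap(ds$cohorts$met, "EwS",
                             ds$truth$planted_target_genes)
  expect_true(all(srm$neglog10p > 2, na.rm = TRUE))
})

test_that("cohort stratification is deterministic and validates inputs", {
  ds <- small_dataset(1)
  sig <- ds$truth$planted_target_genes
  c1 <- stratify_cohort(ds$cohorts$met, sig, n_perm = 150, seed = 3)
  c2 <- stratify_cohort(ds$cohorts$met, sig, n_perm = 150, seed = 3)
  expect_identical(c1, c2)
  expect_error(stratify_cohort(ds$cohorts$met, c("no_such_gene")), "absent")
  expect_error(stratify_cohort(ds$cohorts$kd, sig), ">= 10 samples")
})

test_that("pre-ranked enrichment separates activated from repressed sets", {
  ds <- small_dataset(1)
  # fold-change ranking from the knockdown experiment: planted targets sink
  fc <- fold_change_table(ds$cohorts$kd, ds$pairs)
  ranking <- data.frame(gene = fc$gene_id,
                        metric = -rowMeans(fc[, grep("log2fc", names(fc))]))
  res <- preranked_gsea(ranking,
                        list(activated = ds$truth$planted_target_genes),
                        n_perm = 200, seed = 2)
  expect_lt(res$NES[res$set == "activated"], -1.5)
  expect_lt(res$q[res$set == "activated"], 0.05)
})
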