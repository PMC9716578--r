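pair1 <- data.frame(ctrl = "c1", kd = "k1", stringsAsFactors = FALSE)

kd_matrix <- function(ctrl, kd) {
  # one gene per row of cbind(ctrl, kd), three identical pairs
  m <- cbind(c1 = ctrl, k1 = kd, c2 = ctrl, k2 = kd, c3 = ctrl, k3 = kd)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  toy_expr(m, type_label = "EwS", cohort = "kd")
}

three_pairs <- data.frame(ctrl = c("c1", "c2", "c3"), kd = c("k1", "k2", "k3"),
                          stringsAsFactors = FALSE)

test_that("fold and expression gates use the published boundary semantics", {
  expr <- kd_matrix(ctrl = c(4, 0.9, 4, 3), kd = c(2, 0.1, 3, 0.1))
  # ctrl=4, kd=2: fold exactly 2 meets the inclusive >=2 gate (pseudocount 0)
  res <- common_regulated(expr, three_pairs, "down", pseudocount = 0)
  expect_true("g01" %in% as.character(res))
  # ctrl=0.9 fails the strict >1 FPKM gate regardless of fold
  expect_false("g02" %in% as.character(res))
  # fold 4/3 < 2 fails
  expect_false("g03" %in% as.character(res))
  expect_true("g04" %in% as.character(res))
  expect_identical(res$provenance, "common_down")

  # upregulated direction is symmetric on the knockdown side
  up <- common_regulated(kd_matrix(ctrl = c(2, 0.1), kd = c(4, 0.9)),
                         three_pairs, "up", pseudocount = 0)
  expect_identical(as.character(up), "g01")

  expect_error(common_regulated(expr, three_pairs, min_fold = 0.5), "min_fold")
  bad <- data.frame(ctrl = "nope", kd = "k1")
  expect_error(common_regulated(expr, bad), "nope")
})

test_that("common_regulated equals the naive per-gene, per-pair intersection", {
  set.seed(42)
  m <- matrix(round(2^rnorm(50 * 6, 1, 2), 3), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50),
                              c("c1", "k1", "c2", "k2", "c3", "k3")))
  expr <- toy_expr(m, "EwS", "kd")
  for (dir in c("down", "up")) {
    got <- sort(as.character(common_regulated(expr, three_pairs, dir,
                                              pseudocount = 0.01)))
    want <- character(0)
    for (g in rownames(m)) {
      ok <- TRUE
      for (i in 1:3) {
        ctrl <- m[g, three_pairs$ctrl[i]]; kdv <- m[g, three_pairs$kd[i]]
        ok <- ok && if (dir == "down")
          ctrl > 1 && (ctrl + 0.01) / (kdv + 0.01) >= 2
        else
          kdv > 1 && (kdv + 0.01) / (ctrl + 0.01) >= 2
      }
      if (ok) want <- c(want, g)
    }
    expect_identical(got, sort(want))
  }
})

test_that("cell-line screen removes any off-target expression above the gate", {
  m <- rbind(g1 = c(5, 1.01, 0), g2 = c(5, 1.0, 1.0), g3 = c(5, 0, 5))
  colnames(m) <- c("ews1", "other1", "other2")
  lines <- toy_expr(m, c("EwS", "A", "B"), "lines")
  kept <- specificity_filter_lines(gene_set(rownames(m)), lines, "EwS")
  expect_false("g1" %in% as.character(kept))  # 1.01 in one non-target line
  expect_true("g2" %in% as.character(kept))   # exactly 1.0: strict > retains
  expect_false("g3" %in% as.character(kept))
  expect_error(specificity_filter_lines(gene_set("g1"), lines, "NoSuchType"),
               "NoSuchType")
  # empty candidate set is allowed
  empty <- specificity_filter_lines(gene_set(character(0)), lines, "EwS")
  expect_identical(length(empty), 0L)
})

test_that("cell-line screen equals the naive max-over-non-target check", {
  set.seed(7)
  m <- matrix(round(2^rnorm(40 * 10, 0, 2), 3), 40, 10,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  types <- rep(c("EwS", "A", "B", "C", "D"), 2)
  expr <- toy_expr(m, types, "lines")
  kept <- as.character(specificity_filter_lines(gene_set(rownames(m)), expr, "EwS"))
  want <- rownames(m)[apply(m[, types != "EwS"], 1, max) <= 1]
  expect_identical(sort(kept), sort(want))
})

test_that("type filter counts expressing types via the chosen statistic", {
  # five types, three samples each
  types <- rep(c("EwS", "A", "B", "C", "D"), each = 3)
  m <- rbind(
    only_target = c(9, 9, 9, rep(0, 12)),
    two_types   = c(9, 9, 9, 8, 8, 8, rep(0, 9)),
    outlier     = c(9, 9, 9, 0, 0, 5, rep(0, 9)),  # single off-target sample
    silent      = rep(0, 15))
  colnames(m) <- sprintf("s%02d", 1:15)
  expr <- toy_expr(m, types, "cohort")
  gs <- gene_set(rownames(m))

  kept_med <- as.character(specificity_filter_types(gs, expr, "EwS"))
  expect_true("only_target" %in% kept_med)
  expect_false("two_types" %in% kept_med)          # "more than one" = >= 2 types
  expect_true("outlier" %in% kept_med)             # median absorbs the outlier
  expect_true("silent" %in% kept_med)              # 0 expressing types pass

  kept_any <- as.character(specificity_filter_types(gs, expr, "EwS",
                                                    type_stat = "any"))
  expect_false("outlier" %in% kept_any)            # any-sample mode flags it

  # exhaustive per-type evaluation on a random cohort
  set.seed(11)
  r <- matrix(round(2^rnorm(30 * 15, 0, 2), 3), 30, 15,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:15)))
  rexpr <- toy_expr(r, types, "cohort")
  got <- sort(as.character(specificity_filter_types(gene_set(rownames(r)), rexpr, "EwS")))
  n_types <- sapply(rownames(r), function(g) {
    sum(sapply(unique(types), function(tt) median(r[g, types == tt]) > 1))
  })
  expect_identical(got, sort(names(n_types)[n_types <= 1]))
})

test_that("tissue screen annotates expressing tissues without dropping genes", {
  types <- rep(c("T1", "T2", "T3"), each = 2)
  m <- rbind(silent = rep(0, 6),
             one_tissue = c(5, 5, 0, 0, 0, 0),
             broad = c(5, 5, 5, 5, 5, 5))
  colnames(m) <- sprintf("n%d", 1:6)
  normals <- toy_expr(m, types, "normals")
  res <- tissue_screen(gene_set(rownames(m)), normals)
  expect_identical(sort(as.character(res$genes)), sort(rownames(m)))
  rep_ <- res$report
  expect_equal(rep_$n_tissues[rep_$gene_id == "silent"], 0, ignore_attr = TRUE)
  expect_identical(rep_$tissues[rep_$gene_id == "one_tissue"], "T1")
  expect_false(rep_$flagged[rep_$gene_id == "one_tissue"])
  expect_true(rep_$flagged[rep_$gene_id == "broad"])
  # counts equal a naive per-tissue loop
  for (g in rownames(m)) {
    want <- sum(sapply(unique(types), function(tt) median(m[g, types == tt]) > 1))
    expect_equal(rep_$n_tissues[rep_$gene_id == g], want,
                 ignore_attr = TRUE)
  }
})

test_that("filters are anti-monotone, idempotent and commute", {
  ds <- small_dataset(1)
  all_genes <- gene_set(rownames(fpkm(ds$cohorts$kd)))

  # anti-monotonicity: tightening a threshold never enlarges the output
  loose <- as.character(common_regulated(ds$cohorts$kd, ds$pairs, min_fold = 1.5))
  tight <- as.character(common_regulated(ds$cohorts$kd, ds$pairs, min_fold = 4))
  expect_true(all(tight %in% loose))
  l1 <- as.character(specificity_filter_lines(all_genes, ds$cohorts$lines, "EwS",
                                              max_fpkm = 2))
  l2 <- as.character(specificity_filter_lines(all_genes, ds$cohorts$lines, "EwS",
                                              max_fpkm = 0.5))
  expect_true(all(l2 %in% l1))
  t1 <- as.character(specificity_filter_types(all_genes, ds$cohorts$met, "EwS",
                                              max_other_types = 3))
  t2 <- as.character(specificity_filter_types(all_genes, ds$cohorts$met, "EwS",
                                              max_other_types = 1))
  expect_true(all(t2 %in% t1))

  # idempotence
  once <- specificity_filter_lines(all_genes, ds$cohorts$lines, "EwS")
  twice <- specificity_filter_lines(once, ds$cohorts$lines, "EwS")
  expect_setequal(as.character(once), as.character(twice))

  # composition order-safety: lines o types == types o lines
  a <- specificity_filter_types(
    specificity_filter_lines(all_genes, ds$cohorts$lines, "EwS"),
    ds$cohorts$met, "EwS")
  b <- specificity_filter_lines(
    specificity_filter_types(all_genes, ds$cohorts$met, "EwS"),
    ds$cohorts$lines, "EwS")
  expect_setequal(as.character(a), as.character(b))
})
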