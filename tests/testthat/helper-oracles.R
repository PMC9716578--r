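# Independent oracles used across the suite. Each is deliberately naive
# (regex, exhaustive loops, closed forms) and shares no code with the
# implementation it checks.

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# longest run of tandem motif copies via a greedy regex, optionally on both
# strands
oracle_max_run <- function(seq, motif = "GGAA", both_strands = TRUE) {
  one <- function(s) {
    m <- gregexpr(sprintf("(?:%s)+", motif), s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(0L)
    as.integer(max(attr(m, "match.length")) %/% nchar(motif))
  }
  fwd <- one(seq)
  if (!both_strands) return(fwd)
  max(fwd, one(oracle_revcomp(seq)))
}

# all-pairs peak-to-gene assignment via scalar interval arithmetic
oracle_assign <- function(peaks, ann, window_bp) {
  out <- setNames(vector("list", nrow(ann)), ann$gene_id)
  for (i in seq_len(nrow(ann))) {
    hits <- character(0)
    ws <- ann$tss[i] - window_bp
    we <- ann$tss[i] + window_bp + 1
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != ann$chrom[i]) next
      if (min(we, peaks$end[j]) - max(ws, peaks$start[j]) >= 1)
        hits <- c(hits, peaks$name[j])
    }
    out[[ann$gene_id[i]]] <- hits
  }
  out
}

# textbook Pearson correlation between two vectors
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# closed-form Welch two-sample t statistic and two-sided p
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# step-up Benjamini-Hochberg computed by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exhaustive weighted-KS running sum evaluated at every rank
oracle_es <- function(scores, set_names, p = 1) {
  hit <- names(scores) %in% set_names
  n <- length(scores)
  nh <- sum(hit)
  wh <- abs(scores)^p * hit
  tot <- sum(wh)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) cur + wh[i] / tot else cur - 1 / (n - nh)
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# connected components by breadth-first search over an edge list
oracle_components <- function(nodes, edges) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  nb <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    nb[[edges$from[i]]] <- c(nb[[edges$from[i]]], edges$to[i])
    nb[[edges$to[i]]] <- c(nb[[edges$to[i]]], edges$from[i])
  }
  k <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- k
      queue <- c(queue, nb[[u]])
    }
  }
  comp
}
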