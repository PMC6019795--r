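# Independent scratch implementations used as oracles. These are deliberately
# written loop-by-loop from the definitions, sharing no code with the package
# internals they check.

# t-statistic of one gene for one tissue against the virtual median cell.
oracle_t <- function(vals, tissue_cols, eps = 1e-8) {
  m1 <- stats::median(vals[tissue_cols])
  m2 <- stats::median(vals)
  n1 <- length(tissue_cols)
  n2 <- length(vals)
  v1 <- stats::var(vals[tissue_cols])
  v2 <- stats::var(vals)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  if (sp < eps && abs(m1 - m2) < eps) return(0)
  (m1 - m2) / (sp + eps)
}

# heterogeneity score of one set in one tissue
oracle_hs <- function(mat, labels, set_genes, tissue, fc_threshold, eps = 1e-8) {
  cols <- which(labels == tissue)
  total <- 0
  for (g in intersect(set_genes, rownames(mat))) {
    vals <- mat[g, ]
    m1 <- stats::median(vals[cols])
    m2 <- stats::median(vals)
    if (abs(m1 - m2) >= log2(fc_threshold))
      total <- total + abs(oracle_t(vals, cols, eps))
  }
  total
}

# all permutations of a vector (recursive, no deduplication)
oracle_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in oracle_perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# exact permutation p-values by brute force: every distinct assignment of
# samples to tissue groups (deduplicated by group composition), ties counted
oracle_perm_p <- function(mat, labels, sets_list, fc_threshold) {
  tissues <- unique(labels)
  all_labs <- unique(lapply(oracle_perms(labels), identity))
  keyed <- vapply(all_labs, function(lb)
    paste(vapply(tissues, function(t)
      paste(which(lb == t), collapse = ","), character(1)), collapse = ";"),
    character(1))
  distinct <- all_labs[!duplicated(keyed)]
  p <- matrix(NA_real_, length(sets_list), length(tissues),
              dimnames = list(names(sets_list), tissues))
  for (si in seq_along(sets_list)) for (ti in seq_along(tissues)) {
    obs <- oracle_hs(mat, labels, sets_list[[si]], tissues[ti], fc_threshold)
    cnt <- 0
    for (lb in distinct) {
      names(lb) <- colnames(mat)
      if (oracle_hs(mat, lb, sets_list[[si]], tissues[ti],
                    fc_threshold) >= obs)
        cnt <- cnt + 1
    }
    p[si, ti] <- cnt / length(distinct)
  }
  p
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# AUC as the pairwise Mann-Whitney statistic with half credit for ties
oracle_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# weighted-KS enrichment score by explicit running sum
oracle_es <- function(metric, member) {
  ord <- order(metric, decreasing = TRUE)
  N <- length(metric)
  n <- sum(member)
  wsum <- sum(abs(metric[ord])[member[ord]])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    g <- ord[i]
    if (member[g]) {
      run <- run + if (wsum > 0) abs(metric[g]) / wsum else 1 / n
    } else {
      run <- run - 1 / (N - n)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# MATCH-style matrix similarity score of one window against a frequency
# matrix (4 x L, rows A/C/G/T), straight from the definitions
oracle_mss <- function(freq, window) {
  L <- ncol(freq)
  bases <- c("A", "C", "G", "T")
  info <- numeric(L)
  for (i in seq_len(L))
    info[i] <- sum(freq[, i] * log(4 * freq[, i]))
  cur <- mn <- mx <- 0
  for (i in seq_len(L)) {
    cur <- cur + info[i] * freq[match(window[i], bases), i]
    mn <- mn + info[i] * min(freq[, i])
    mx <- mx + info[i] * max(freq[, i])
  }
  if (mx - mn <= 1e-12) return(0)
  unname((cur - mn) / (mx - mn))
}

# convenience builders -------------------------------------------------------

toy_expr <- function(values, tissues) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, tissues)
}

random_pwm <- function(L = 8, seed = NULL, id = "m") {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::rgamma(4 * L, shape = 1) * 20, 4, L)
  pwm(counts, motif_id = id)
}

revcomp_seq <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

BASES <- c("A", "C", "G", "T")

consensus_pwm <- function(consensus, hi = 94, lo = 2, id = "m") {
  ch <- strsplit(consensus, "")[[1]]
  counts <- matrix(lo, 4, length(ch), dimnames = list(BASES, NULL))
  counts[cbind(match(ch, BASES), seq_along(ch))] <- hi
  pwm(counts, motif_id = id)
}

consensus_of <- function(p) paste(BASES[apply(p$freq, 2, which.max)],
                                  collapse = "")
anticonsensus_of <- function(p) paste(BASES[apply(p$freq, 2, which.min)],
                                      collapse = "")

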