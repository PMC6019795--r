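#' Parametric average-fold-change enrichment scores (PGSEA-like)
#'
#' Per sample, each gene's fold change is its value minus its median across
#' all samples (log2 space). A set's per-sample score is the one-sample
#' t-statistic of its members' fold changes against zero, with a two-sided
#' p-value from the t distribution on `n_set - 1` degrees of freedom. The
#' per-tissue score is the mean of the tissue's per-sample scores, with a
#' p-value from the same reference distribution. This is a minimal
#' re-derivation of the average-fold-change test, labeled `"pgsea-like"` in
#' the output; exact parity with the published package is not attempted.
#'
#' Degenerate sets: fewer than 2 measured members gives a missing score (with
#' a warning); a zero standard deviation of fold changes is floored at `eps`,
#' and p-values are floored at 1e-15.
#'
#' @param expr An [expression_matrix()] object.
#' @param sets A [gene_sets()] collection.
#' @param eps Floor for the fold-change standard deviation (default 1e-8).
#' @return List with `tissue` (data frame: set, tissue, score, p, method),
#'   `sample_scores` and `sample_p` (sets x samples matrices).
#' @export
pgsea_scores <- function(expr, sets, eps = 1e-8) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "gene_sets"))
  v <- expr$values
  fc <- v - apply(v, 1L, stats::median)
  des <- tissue_design(expr)
  score <- pmat <- matrix(NA_real_, length(sets), ncol(v),
                          dimnames = list(names(sets), colnames(v)))
  df <- integer(length(sets))
  for (j in seq_along(sets)) {
    idx <- match(sets[[j]], rownames(v))
    idx <- idx[!is.na(idx)]
    k <- length(idx)
    if (k < 2) {
      warning("set '", names(sets)[j],
              "' has fewer than 2 measured genes; score undefined")
      next
    }
    x <- fc[idx, , drop = FALSE]
    mu <- colMeans(x)
    sdv <- pmax(sqrt((colSums(x * x) - k * mu * mu) / (k - 1)), eps)
    score[j, ] <- mu / (sdv / sqrt(k))
    pmat[j, ] <- pmax(2 * stats::pt(-abs(score[j, ]), df = k - 1), 1e-15)
    df[j] <- k - 1
  }
  rows <- list()
  for (g in seq_along(des$tissues)) {
    cols <- match(des$replicates[[g]], colnames(v))
    ts <- rowMeans(score[, cols, drop = FALSE])
    tp <- ifelse(df > 0,
                 pmax(2 * stats::pt(-abs(ts), df = pmax(df, 1)), 1e-15),
                 NA_real_)
    rows[[g]] <- data.frame(set = names(sets), tissue = des$tissues[g],
                            score = unname(ts), p = unname(tp),
                            method = "pgsea-like", stringsAsFactors = FALSE)
  }
  list(tissue = do.call(rbind, rows), sample_scores = score, sample_p = pmat)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight exponent
# 1). metric: named per-gene ranking values; member: logical, same length.
# Hits climb proportionally to |metric| (normalized over the set), misses
# step down 1/(N - n); ES is the running sum at its maximum absolute
# deviation. A set equal to the whole universe has no misses (miss step 0).
gsea_es <- function(metric, member) {
  ord <- order(metric, decreasing = TRUE)
  hit <- member[ord]
  w <- abs(metric[ord]) * hit
  tot <- sum(w)
  n <- sum(member)
  N <- length(metric)
  inc <- if (tot > 0) w / tot else hit / n
  dec <- if (N > n) (!hit) / (N - n) else 0
  run <- cumsum(inc - dec)
  unname(run[which.max(abs(run))])
}

#' Weighted-KS enrichment scores with phenotype permutation (GSEA-like)
#'
#' Per tissue, genes are ranked by the pooled-variance two-sample t-statistic
#' of the tissue's samples against all other samples. The enrichment score of
#' a set is the signed maximum deviation of the weighted Kolmogorov-Smirnov
#' running sum over that ranking (weight exponent 1). Significance is
#' assessed by phenotype permutation — the sample-to-tissue assignment is
#' permuted under the same arrangement scheme as the heterogeneity test, the
#' metric and enrichment score are recomputed, and the two-sided p-value is
#' the fraction of permutations with `|ES| >= |ES_obs|` (add-one Monte Carlo
#' estimator, or the exact fraction when the design is enumerated
#' exhaustively). Labeled `"gsea-like"`; parity with the published
#' implementation is not attempted.
#'
#' @inheritParams pgsea_scores
#' @param n_perm Monte Carlo permutations (default 1000).
#' @param seed Optional integer seed.
#' @param exhaustive_cap Enumerate all arrangements when their count is at
#'   most this (default 10000).
#' @return List with `tissue` (data frame: set, tissue, es, p, method) and
#'   `es` (sets x tissues matrix).
#' @export
gsea_enrichment <- function(expr, sets, n_perm = 1000, seed = NULL,
                            exhaustive_cap = 10000, eps = 1e-8) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "gene_sets"))
  v <- expr$values
  des <- tissue_design(expr)
  if (any(lengths(sets) > nrow(v)))
    stop("gene set larger than the measured gene universe")
  groups0 <- lapply(des$replicates, function(s) match(s, colnames(v)))
  sizes <- lengths(groups0)
  members <- lapply(sets, function(g) rownames(v) %in% g)

  es_all <- function(groups) {
    out <- matrix(NA_real_, length(sets), length(groups),
                  dimnames = list(names(sets), des$tissues))
    for (g in seq_along(groups)) {
      met <- two_sample_t(v, groups[[g]], eps)
      for (j in seq_along(sets)) out[j, g] <- gsea_es(met, members[[j]])
    }
    out
  }
  es_obs <- es_all(groups0)

  n_arr <- count_arrangements(sizes)
  exhaustive <- n_arr <= exhaustive_cap
  geq <- matrix(0, length(sets), length(des$tissues))
  if (exhaustive) {
    arr <- enumerate_arrangements(sizes)
    for (a in seq_len(ncol(arr))) {
      groups <- lapply(seq_along(sizes), function(g) which(arr[, a] == g))
      geq <- geq + (abs(es_all(groups)) >= abs(es_obs))
    }
    p <- geq / ncol(arr)
  } else {
    if (!is.null(seed)) set.seed(seed)
    asg0 <- integer(ncol(v))
    for (g in seq_along(groups0)) asg0[groups0[[g]]] <- g
    for (b in seq_len(n_perm)) {
      asg <- sample(asg0)
      groups <- lapply(seq_along(sizes), function(g) which(asg == g))
      geq <- geq + (abs(es_all(groups)) >= abs(es_obs))
    }
    p <- (1 + geq) / (1 + n_perm)
  }
  dimnames(p) <- dimnames(es_obs)
  tissue <- data.frame(
    set = rep(rownames(es_obs), times = ncol(es_obs)),
    tissue = rep(colnames(es_obs), each = nrow(es_obs)),
    es = as.vector(es_obs), p = as.vector(p),
    method = "gsea-like", stringsAsFactors = FALSE)
  list(tissue = tissue, es = es_obs)
}

# Pooled-variance two-sample t of columns `cols` against the rest, per gene.
two_sample_t <- function(v, cols, eps = 1e-8) {
  x <- v[, cols, drop = FALSE]
  y <- v[, -cols, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  sp <- sqrt(((n1 - 1) * row_vars(x) + (n2 - 1) * row_vars(y)) /
               (n1 + n2 - 2))
  num <- m1 - m2
  tt <- num / ((sp + eps) * sqrt(1 / n1 + 1 / n2))
  tt[sp < eps & abs(num) < eps] <- 0
  tt
}
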