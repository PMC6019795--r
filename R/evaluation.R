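#' Consensus ground truth from comparator q-values
#'
#' Labels gene sets as positive when their FDR-adjusted comparator values are
#' below `pos_cut`, and negative when above `neg_cut`, in both comparators
#' (default rule) or in either one; everything else is ambiguous and excluded
#' from ROC evaluation.
#'
#' @param gsea_q,pgsea_q Named numeric vectors of q-values over the same
#'   sets.
#' @param pos_cut Positive threshold (default 0.01).
#' @param neg_cut Negative threshold (default 0.2).
#' @param rule `"both"` (default, conservative: the comparators must agree)
#'   or `"either"`.
#' @return A list of class `"ground_truth"` with character vectors
#'   `positives`, `negatives`, `ambiguous`.
#' @export
consensus_ground_truth <- function(gsea_q, pgsea_q, pos_cut = 0.01,
                                   neg_cut = 0.2,
                                   rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (is.null(names(gsea_q)) || is.null(names(pgsea_q)))
    stop("q-value vectors must be named by set")
  common <- intersect(names(gsea_q), names(pgsea_q))
  if (!setequal(names(gsea_q), names(pgsea_q)))
    stop("the two q tables must cover the same sets")
  g <- gsea_q[common]; p <- pgsea_q[common]
  comb <- if (rule == "both") `&` else `|`
  pos <- comb(g < pos_cut, p < pos_cut)
  neg <- comb(g > neg_cut, p > neg_cut)
  neg <- neg & !pos   # "either" could satisfy both; positive wins
  structure(list(positives = common[pos], negatives = common[neg],
                 ambiguous = common[!pos & !neg]),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d positive, %d negative, %d ambiguous\n",
              length(x$positives), length(x$negatives), length(x$ambiguous)))
  invisible(x)
}

#' ROC curve and AUC of a set-level score against a ground truth
#'
#' Scores are oriented so that higher means more positive (the default input
#' is the heterogeneity score). Points are swept over the distinct score
#' thresholds; tied scores contribute diagonal segments, so the trapezoidal
#' AUC equals the Mann-Whitney statistic with half credit for ties,
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Named numeric vector of per-set scores (must cover the truth
#'   sets).
#' @param truth A [consensus_ground_truth()] object (ambiguous sets are
#'   ignored).
#' @return A list of class `"roc_result"`: `points` (data frame of fpr, tpr,
#'   ascending), `auc`, and counts `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  labs <- c(stats::setNames(rep(TRUE, length(truth$positives)),
                            truth$positives),
            stats::setNames(rep(FALSE, length(truth$negatives)),
                            truth$negatives))
  if (!length(truth$positives) || !length(truth$negatives))
    stop("ROC undefined: need at least one positive and one negative set")
  missing <- setdiff(names(labs), names(scores))
  if (length(missing))
    stop("no score for set(s): ", paste(missing, collapse = ", "))
  s <- scores[names(labs)]
  if (length(unique(s)) == 1)
    warning("all scores identical: AUC = 0.5")
  n_pos <- sum(labs); n_neg <- sum(!labs)
  # Mann-Whitney via midranks (ties get half credit)
  r <- rank(s)
  auc <- (sum(r[labs]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # ROC sweep over distinct thresholds, descending
  ord <- order(s, decreasing = TRUE)
  sl <- labs[ord]; ss <- s[ord]
  tp <- cumsum(sl); fp <- cumsum(!sl)
  keep <- c(diff(ss) != 0, TRUE)   # last index of each tied block
  pts <- data.frame(fpr = c(0, fp[keep] / n_neg),
                    tpr = c(0, tp[keep] / n_pos))
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Permutation significance of an AUC
#'
#' Permutes the positive/negative labels over the scored sets and recomputes
#' the AUC; the p-value is the fraction of permuted AUCs at least as large as
#' the observed one. When the number of distinct label arrangements
#' (`choose(n, n_pos)`) is at most `exhaustive_cap`, all are enumerated and
#' the p-value is the exact fraction (the identity arrangement counts, so
#' `p > 0`); otherwise Monte Carlo over `n_perm` draws, floored at
#' `1/n_perm`.
#'
#' @inheritParams roc_auc
#' @param n_perm Monte Carlo permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed Optional integer seed.
#' @param exhaustive_cap Enumerate exhaustively at or below this many
#'   arrangements (default 10000).
#' @return List with `p`, `auc_obs`, `n_used` and `exhaustive`.
#' @export
auc_permutation_test <- function(scores, truth, n_perm = 1000, seed = NULL,
                                 exhaustive_cap = 10000) {
  if (n_perm < 100) warning("n_perm < 100: permutation p will be coarse")
  obs <- roc_auc(scores, truth)
  labs <- c(rep(TRUE, obs$n_pos), rep(FALSE, obs$n_neg))
  s <- scores[c(truth$positives, truth$negatives)]
  n <- length(s)
  r <- rank(s)
  auc_of <- function(pos_idx)
    (sum(r[pos_idx]) - obs$n_pos * (obs$n_pos + 1) / 2) /
      (obs$n_pos * obs$n_neg)
  n_arr <- choose(n, obs$n_pos)
  if (n_arr <= exhaustive_cap) {
    picks <- utils::combn(n, obs$n_pos, simplify = FALSE)
    aucs <- vapply(picks, auc_of, numeric(1))
    p <- mean(aucs >= obs$auc)
    list(p = p, auc_obs = obs$auc, n_used = length(picks), exhaustive = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    geq <- 0
    for (b in seq_len(n_perm))
      geq <- geq + (auc_of(sample.int(n, obs$n_pos)) >= obs$auc)
    list(p = max(geq / n_perm, 1 / n_perm), auc_obs = obs$auc,
         n_used = n_perm, exhaustive = FALSE)
  }
}

#' ROC/AUC evaluation of a heterogeneity fit at several fold-change thresholds
#'
#' Re-runs the heterogeneity scoring at each fold-change threshold, pools the
#' per-(set, tissue) scores (maximum over tissues per set by default, so one
#' score per set), and evaluates them against a comparator-derived ground
#' truth.
#'
#' @param expr An [expression_matrix()].
#' @param sets A [gene_sets()] collection.
#' @param truth A [consensus_ground_truth()].
#' @param fc_thresholds Numeric vector of fold-change thresholds
#'   (default `c(1.5, 2, 3)`).
#' @param n_perm Permutations for the AUC significance test (default 1000).
#' @param seed Optional integer seed.
#' @return Data frame with one row per threshold: `fc_threshold`, `auc`,
#'   `auc_p`, `n_pos`, `n_neg`.
#' @export
evaluate_roc <- function(expr, sets, truth, fc_thresholds = c(1.5, 2, 3),
                         n_perm = 1000, seed = NULL) {
  out <- lapply(fc_thresholds, function(fc) {
    st <- tissue_t_statistics(expr, fc_threshold = fc)
    hs <- heterogeneity_scores(st, sets)$hs
    score <- apply(hs, 1L, max)
    r <- roc_auc(score, truth)
    pt <- auc_permutation_test(score, truth, n_perm = n_perm, seed = seed)
    data.frame(fc_threshold = fc, auc = r$auc, auc_p = pt$p,
               n_pos = r$n_pos, n_neg = r$n_neg)
  })
  do.call(rbind, out)
}
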