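# MATCH-style scoring. Per-position information weights
#   I(i) = sum_b f(i,b) * ln(4 * f(i,b))
# score a window (b_1..b_L) by Current = sum_i I(i) * f(i, b_i) and normalize
#   MSS = (Current - Min) / (Max - Min)
# where Min/Max sum the per-position minimal/maximal weighted frequencies.
# The core similarity score (CSS) applies the same formula restricted to the
# core: the 5 consecutive positions with the largest total information
# (leftmost window on ties). An all-uniform matrix has Max = Min; its windows
# score 0 and never match.
pwm_profile <- function(p, core_width = 5) {
  f <- p$freq
  L <- ncol(f)
  info <- colSums(f * log(4 * f))
  W <- f * rep(info, each = 4)           # weighted frequencies, 4 x L
  lo <- info * apply(f, 2, min)
  hi <- info * apply(f, 2, max)
  cw <- min(core_width, L)
  csum <- vapply(seq_len(L - cw + 1),
                 function(i) sum(info[i:(i + cw - 1)]), numeric(1))
  core <- which.max(csum) + seq_len(cw) - 1
  list(W = W, min = sum(lo), max = sum(hi),
       core = core, core_min = sum(lo[core]), core_max = sum(hi[core]),
       L = L)
}

# Similarity scores of every window of an encoded sequence (integer codes
# 1..4, NA for N) against a profile. Windows touching an N score NA.
window_scores <- function(code, prof) {
  L <- prof$L
  n_win <- length(code) - L + 1
  if (n_win < 1)
    return(list(mss = numeric(0), css = numeric(0)))
  cur <- numeric(n_win)
  curc <- numeric(n_win)
  for (j in seq_len(L)) {
    b <- code[j:(j + n_win - 1)]
    cur <- cur + prof$W[, j][b]
    if (j %in% prof$core) curc <- curc + prof$W[, j][b]
  }
  den <- prof$max - prof$min
  denc <- prof$core_max - prof$core_min
  mss <- if (den > 1e-12) (cur - prof$min) / den else rep(0, n_win) * cur
  css <- if (denc > 1e-12) (curc - prof$core_min) / denc
         else rep(0, n_win) * curc
  # scores live in [0, 1] by construction; clip float residue at the ends
  list(mss = pmin(pmax(mss, 0), 1), css = pmin(pmax(css, 0), 1))
}

encode_dna <- function(seq) match(strsplit(seq, "")[[1]], DNA_BASES)

#' Scan a promoter sequence for PWM matches (MATCH-style)
#'
#' Scores every window on both strands with the matrix similarity score
#' (MSS) and the core similarity score (CSS), both in `[0, 1]`; a hit
#' requires `MSS >= cutoff` and `CSS >= cutoff`. The consensus window (the
#' highest-frequency base at every position) scores MSS = 1 and the
#' anti-consensus scores 0. Minus-strand windows are scored with the
#' reverse-complemented matrix; the reported position is the 1-based start of
#' the window on the supplied sequence. Windows containing N never match. A
#' motif longer than the sequence yields an empty result.
#'
#' @param seq A nucleotide sequence (character scalar, A/C/G/T/N).
#' @param pwm A [pwm()] object.
#' @param cutoff Similarity cutoff in `[0, 1]` (default 0.7, the conventional
#'   threshold for calling a putative binding site).
#' @return Data frame with columns `motif_id`, `position`, `strand`, `mss`,
#'   `css`, one row per hit.
#' @export
scan_promoter <- function(seq, pwm, cutoff = 0.7) {
  stopifnot(inherits(pwm, "pwm"))
  if (cutoff < 0 || cutoff > 1) stop("'cutoff' must be in [0, 1]")
  seq <- toupper(seq)
  code <- encode_dna(seq)
  fw <- window_scores(code, pwm_profile(pwm))
  rv <- window_scores(code, pwm_profile(reverse_complement_pwm(pwm)))
  hit_rows <- function(sc, strand) {
    ok <- which(!is.na(sc$mss) & sc$mss >= cutoff &
                  !is.na(sc$css) & sc$css >= cutoff)
    data.frame(motif_id = rep(pwm$id, length(ok)), position = ok,
               strand = rep(strand, length(ok)),
               mss = sc$mss[ok], css = sc$css[ok], stringsAsFactors = FALSE)
  }
  rbind(hit_rows(fw, "+"), hit_rows(rv, "-"))
}

#' Scan a promoter set for PWM matches
#'
#' @param promoters A [promoter_set()].
#' @param pwm A [pwm()] object.
#' @param cutoff Similarity cutoff (default 0.7).
#' @return Data frame as in [scan_promoter()] with an additional leading
#'   `gene_id` column.
#' @export
scan_promoters <- function(promoters, pwm, cutoff = 0.7) {
  stopifnot(inherits(promoters, "promoter_set"))
  out <- lapply(names(promoters), function(g) {
    h <- scan_promoter(promoters[[g]], pwm, cutoff)
    if (nrow(h)) cbind(gene_id = g, h, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), motif_id = character(),
                      position = integer(), strand = character(),
                      mss = numeric(), css = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Motif over-representation in target promoters versus a background
#'
#' The statistic is the number of target promoters carrying at least one
#' passing hit. The null distribution is the same statistic on `n_draws`
#' random draws of `|targets|` sequences (without replacement) from the
#' background set; the empirical p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_draws)`, so `p > 0`.
#' `p < 0.05` is the conventional over-representation call.
#'
#' @param targets,background [promoter_set()]s; the background must be at
#'   least as large as the target set.
#' @param pwm A [pwm()] object.
#' @param cutoff Similarity cutoff for a hit (default 0.7).
#' @param n_draws Background draws (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `"enrichment_result"`: `motif_id`,
#'   `observed_hits`, `background_mean`, `p`, `n_targets`, `n_draws`.
#' @export
motif_enrichment <- function(targets, background, pwm, cutoff = 0.7,
                             n_draws = 1000, seed = NULL) {
  stopifnot(inherits(targets, "promoter_set"),
            inherits(background, "promoter_set"))
  if (length(background) < length(targets))
    stop("background must contain at least as many sequences as targets")
  if (!is.null(seed)) set.seed(seed)
  has_hit <- function(ps) vapply(unclass(ps), function(s)
    nrow(scan_promoter(s, pwm, cutoff)) > 0, logical(1))
  obs <- sum(has_hit(targets))
  bg_hit <- has_hit(background)
  k <- length(targets)
  null_stat <- vapply(seq_len(n_draws), function(b)
    sum(bg_hit[sample.int(length(bg_hit), k)]), numeric(1))
  structure(list(motif_id = pwm$id, observed_hits = obs,
                 background_mean = mean(null_stat),
                 p = (1 + sum(null_stat >= obs)) / (1 + n_draws),
                 n_targets = k, n_draws = n_draws),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "motif '%s': %d/%d target promoters hit (background mean %.1f), p = %.4g\n",
    x$motif_id, x$observed_hits, x$n_targets, x$background_mean, x$p))
  invisible(x)
}

#' Cutoff minimizing the sum of false-positive and false-negative rates
#'
#' Positive sequences are sampled position-by-position from the PWM's column
#' distributions (motif-length sequences, scored as single forward windows);
#' the false-negative percentage at a cutoff is the fraction of positives
#' with MSS below it. The false-positive percentage is the fraction of
#' forward-strand background windows with MSS at or above the cutoff. The
#' returned cutoff minimizes FN% + FP% over the grid 0.50 to 1.00 in steps
#' of 0.01, taking the largest cutoff on ties.
#'
#' @param pwm A [pwm()] object.
#' @param background A non-empty [promoter_set()] of background sequences.
#' @param n_positive PWM-sampled positive sequences (default 1000).
#' @param seed Optional integer seed.
#' @return The selected cutoff, with the grid search table (`cutoff`,
#'   `fn_pct`, `fp_pct`) attached as attribute `"table"`.
#' @export
minsum_cutoff <- function(pwm, background, n_positive = 1000, seed = NULL) {
  stopifnot(inherits(pwm, "pwm"), inherits(background, "promoter_set"))
  if (!length(background)) stop("background must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  prof <- pwm_profile(pwm)
  L <- prof$L
  pos_scores <- vapply(seq_len(n_positive), function(b) {
    code <- apply(pwm$freq, 2, function(f) sample.int(4, 1, prob = f))
    window_scores(code, prof)$mss
  }, numeric(1))
  bg_scores <- unlist(lapply(unclass(background), function(s)
    window_scores(encode_dna(s), prof)$mss), use.names = FALSE)
  bg_scores <- bg_scores[!is.na(bg_scores)]
  grid <- seq(0.50, 1.00, by = 0.01)
  fn <- vapply(grid, function(c) 100 * mean(pos_scores < c), numeric(1))
  fp <- vapply(grid, function(c) 100 * mean(bg_scores >= c), numeric(1))
  tot <- fn + fp
  best <- max(which(tot <= min(tot) + 1e-12))   # ties -> larger cutoff
  structure(grid[best],
            table = data.frame(cutoff = grid, fn_pct = fn, fp_pct = fp))
}

#' Tissue-specific transcription-factor regulatory network edges
#'
#' For every significant heterogeneous set in a tissue (`q < alpha` in the
#' fit), draws edges from each candidate transcription factor to the set's
#' heterogeneous member genes carrying a promoter hit for the factor's
#' motif. A factor qualifies only when its motif is over-represented
#' (`enrichment p < enrichment_alpha`) and the factor itself is upregulated
#' in the tissue (`t > 0` and passing the fold-change filter) — an enriched
#' motif whose factor is not expressed in the tissue emits no edges.
#'
#' @param fit A [heteropath()] fit (on the expression matrix that also
#'   measures the transcription factors).
#' @param tf_motif_map Data frame mapping factors to motifs: columns `tf`,
#'   `motif_id` and optionally `evidence` (`"annotated"` for curated
#'   pairs; anything absent defaults to `"putative"`). Several factors may
#'   share a motif.
#' @param enrichment Data frame with columns `motif_id` and `p` (e.g. rows
#'   built from [motif_enrichment()] results).
#' @param hits Data frame of promoter hits with columns `gene_id` and
#'   `motif_id` (from [scan_promoters()]).
#' @param alpha FDR threshold for a significant heterogeneous set
#'   (default 0.05).
#' @param enrichment_alpha Motif over-representation threshold
#'   (default 0.05).
#' @return Data frame of unique edges: `tf`, `target`, `tissue`, `motif_id`,
#'   `evidence`, `tf_expressed`.
#' @export
build_network <- function(fit, tf_motif_map, enrichment, hits,
                          alpha = 0.05, enrichment_alpha = 0.05) {
  stopifnot(inherits(fit, "heteropath"))
  if (is.null(tf_motif_map) || !nrow(tf_motif_map))
    stop("empty tf_motif_map: supply a two-column (tf, motif_id) table, ",
         "e.g. exported from a curated motif database")
  if (is.null(tf_motif_map$evidence)) tf_motif_map$evidence <- "putative"
  pass <- fit$stats$pass_fc
  tmat <- fit$stats$t
  sig <- summary(fit, alpha = alpha)
  enriched <- enrichment$motif_id[enrichment$p < enrichment_alpha]
  edges <- list()
  for (r in seq_len(nrow(sig))) {
    tis <- sig$tissue[r]
    # heterogeneous member genes of this set in this tissue
    genes <- intersect(fit$sets[[sig$set[r]]], rownames(pass))
    genes <- genes[pass[genes, tis]]
    if (!length(genes)) next
    for (k in seq_len(nrow(tf_motif_map))) {
      tf <- tf_motif_map$tf[k]
      motif <- tf_motif_map$motif_id[k]
      if (!motif %in% enriched) next
      if (!tf %in% rownames(tmat)) next
      if (!(tmat[tf, tis] > 0 && pass[tf, tis])) next
      targets <- intersect(genes,
                           hits$gene_id[hits$motif_id == motif])
      if (!length(targets)) next
      edges[[length(edges) + 1]] <- data.frame(
        tf = tf, target = targets, tissue = tis, motif_id = motif,
        evidence = tf_motif_map$evidence[k], tf_expressed = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(tf = character(), target = character(),
                      tissue = character(), motif_id = character(),
                      evidence = character(), tf_expressed = logical(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, edges))
}
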