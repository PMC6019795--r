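#' Describe a pathway to plant in a synthetic expression fixture
#'
#' @param name Set name the planted pathway will carry in the collection.
#' @param tissue Target tissue receiving the perturbation.
#' @param size Number of member genes (default 50).
#' @param frac_up,frac_down Fractions of members shifted up / down
#'   (default 0.5 each, i.e. a mean-zero bidirectional perturbation). Their
#'   sum must not exceed 1; the remainder stays unshifted.
#' @param effect Log2 shift magnitude applied to the target tissue
#'   (default 1, a two-fold change).
#' @return A list of class `"planted_pathway"`.
#' @export
planted_pathway <- function(name, tissue, size = 50, frac_up = 0.5,
                            frac_down = 0.5, effect = 1) {
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1)
    stop("planted fractions must be non-negative with frac_up + frac_down <= 1")
  if (size < 1) stop("planted pathway needs >= 1 gene")
  structure(list(name = name, tissue = tissue, size = size,
                 frac_up = frac_up, frac_down = frac_down, effect = effect),
            class = "planted_pathway")
}

#' Configuration for the synthetic expression fixture generator
#'
#' @param n_genes Total genes (default 2000).
#' @param tissues Tissue labels (default three tissues).
#' @param replicates Samples per tissue (default 3).
#' @param n_sets Number of decoy gene sets drawn at random from the gene
#'   universe (default 20).
#' @param set_size Genes per decoy set (default 50).
#' @param planted List of [planted_pathway()] descriptions (default none).
#' @param noise_sd Baseline noise standard deviation in log2 units
#'   (default 0.25).
#' @param gene_effect_sd Standard deviation of the per-gene baseline level
#'   (default 1).
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_genes = 2000, tissues = c("t1", "t2", "t3"),
                           replicates = 3, n_sets = 20, set_size = 50,
                           planted = list(), noise_sd = 0.25,
                           gene_effect_sd = 1) {
  if (inherits(planted, "planted_pathway")) planted <- list(planted)
  for (p in planted) {
    stopifnot(inherits(p, "planted_pathway"))
    if (!p$tissue %in% tissues)
      stop("planted tissue '", p$tissue, "' not among the fixture tissues")
  }
  if (sum(vapply(planted, function(p) p$size, numeric(1))) > n_genes)
    stop("planted pathways need more genes than the fixture has")
  structure(list(n_genes = n_genes, tissues = tissues,
                 replicates = replicates, n_sets = n_sets,
                 set_size = set_size, planted = planted,
                 noise_sd = noise_sd, gene_effect_sd = gene_effect_sd),
            class = "fixture_config")
}

#' Generate a synthetic expression fixture with planted pathways
#'
#' Baseline expression for gene `i` in every sample is
#' `N(mu = gene effect, sd = noise_sd)` with the gene effect itself drawn
#' `N(0, gene_effect_sd)` — a flat landscape in which every tissue's median
#' matches the global median up to sampling noise. Each planted pathway adds
#' `+effect` to a fraction of its member genes and `-effect` to another
#' fraction, only in the samples of the target tissue; an equal up/down split
#' plants a mean-zero bidirectional perturbation, the scenario mean-shift
#' enrichment scores cannot see. Decoy sets are random draws from the full
#' gene universe. Output is deterministic given `seed` (Mersenne-Twister).
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @return List with `expr` ([expression_matrix()]), `sets` ([gene_sets()],
#'   decoys plus one set per planted pathway), and `truth` — a list with
#'   `planted` (data frame of set, tissue, effect) and `shifted` (data frame
#'   of gene, set, direction).
#' @export
generate_fixture <- function(config, seed) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(seed, kind = "Mersenne-Twister")
  cf <- config
  genes <- sprintf("g%05d", seq_len(cf$n_genes))
  samples <- paste0(rep(cf$tissues, each = cf$replicates), "_r",
                    rep(seq_len(cf$replicates), times = length(cf$tissues)))
  tissue <- stats::setNames(rep(cf$tissues, each = cf$replicates), samples)
  alpha <- stats::rnorm(cf$n_genes, 0, cf$gene_effect_sd)
  v <- matrix(stats::rnorm(cf$n_genes * length(samples), alpha, cf$noise_sd),
              cf$n_genes, length(samples),
              dimnames = list(genes, samples))

  sets <- list()
  shifted <- list()
  pool <- genes
  for (p in cf$planted) {
    members <- sample(pool, p$size)
    pool <- setdiff(pool, members)
    n_up <- round_half_up(p$frac_up * p$size)
    n_down <- min(round_half_up(p$frac_down * p$size), p$size - n_up)
    up <- members[seq_len(n_up)]
    down <- members[n_up + seq_len(n_down)]
    cols <- which(tissue == p$tissue)
    v[up, cols] <- v[up, cols] + p$effect
    v[down, cols] <- v[down, cols] - p$effect
    sets[[p$name]] <- members
    shifted[[p$name]] <- data.frame(
      gene = c(up, down), set = p$name,
      direction = rep(c("up", "down"), c(n_up, n_down)),
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(cf$n_sets))
    sets[[sprintf("decoy%02d", k)]] <- sample(genes, cf$set_size)

  planted_df <- data.frame(
    set = vapply(cf$planted, `[[`, character(1), "name"),
    tissue = vapply(cf$planted, `[[`, character(1), "tissue"),
    effect = vapply(cf$planted, `[[`, numeric(1), "effect"),
    stringsAsFactors = FALSE)
  list(expr = expression_matrix(v, tissue),
       sets = gene_sets(sets),
       truth = list(planted = planted_df,
                    shifted = do.call(rbind, c(shifted,
                                               make.row.names = FALSE))))
}

round_half_up <- function(x) floor(x + 0.5)

#' Configuration for the synthetic promoter fixture generator
#'
#' @param seq_length Promoter length in bp (default 500).
#' @param n_targets,n_background Number of target / background promoters
#'   (defaults 50 and 500).
#' @param consensus Motif consensus sequence (A/C/G/T string, default a
#'   12-mer); the generated PWM gives the consensus base `strength` of the
#'   column's counts and splits the rest evenly.
#' @param strength Fraction of counts on the consensus base per column
#'   (default 0.95).
#' @param fraction Fraction of target promoters carrying one embedded motif
#'   instance (default 0.8).
#' @return A list of class `"promoter_fixture_config"`.
#' @export
promoter_fixture_config <- function(seq_length = 500, n_targets = 50,
                                    n_background = 500,
                                    consensus = "TGACGTCATGCA",
                                    strength = 0.95, fraction = 0.8) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus))
    stop("consensus must use the A/C/G/T alphabet")
  if (nchar(consensus) > seq_length)
    stop("motif longer than the promoter sequence")
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  structure(list(seq_length = seq_length, n_targets = n_targets,
                 n_background = n_background, consensus = consensus,
                 strength = strength, fraction = fraction),
            class = "promoter_fixture_config")
}

#' Generate synthetic target and background promoter sets with a planted motif
#'
#' Background promoters are i.i.d. uniform over A/C/G/T. Target promoters are
#' generated the same way, except that in `fraction` of them one motif
#' instance, sampled position-by-position from the PWM's column
#' distributions, replaces the sequence at a uniformly random start
#' position. Deterministic given `seed`.
#'
#' @param config A [promoter_fixture_config()].
#' @param seed Integer seed.
#' @return List with `targets` and `background` ([promoter_set()]s), `pwm`
#'   (the planted motif as a [pwm()]), and `truth` — data frame of target
#'   gene, embedded flag and start position (`NA` when not embedded).
#' @export
generate_promoter_fixture <- function(config, seed) {
  stopifnot(inherits(config, "promoter_fixture_config"))
  set.seed(seed, kind = "Mersenne-Twister")
  cf <- config
  L <- nchar(cf$consensus)
  cons <- strsplit(cf$consensus, "")[[1]]
  counts <- matrix((1 - cf$strength) * 100 / 3, 4, L,
                   dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(cons, DNA_BASES), seq_len(L))] <- cf$strength * 100
  motif <- pwm(counts, motif_id = "planted")

  rand_seq <- function(n)
    vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, cf$seq_length, replace = TRUE), collapse = ""),
      character(1))
  bg <- rand_seq(cf$n_background)
  names(bg) <- sprintf("bg%04d", seq_len(cf$n_background))
  tg <- rand_seq(cf$n_targets)
  names(tg) <- sprintf("tg%04d", seq_len(cf$n_targets))

  n_embed <- round_half_up(cf$fraction * cf$n_targets)
  embed_idx <- if (n_embed > 0) sample(cf$n_targets, n_embed) else integer(0)
  pos <- rep(NA_integer_, cf$n_targets)
  for (i in embed_idx) {
    inst <- paste(DNA_BASES[apply(motif$freq, 2, function(f)
      sample.int(4, 1, prob = f))], collapse = "")
    start <- sample.int(cf$seq_length - L + 1, 1)
    substr(tg[i], start, start + L - 1) <- inst
    pos[i] <- start
  }
  list(targets = promoter_set(tg), background = promoter_set(bg),
       pwm = motif,
       truth = data.frame(gene = names(tg),
                          embedded = seq_len(cf$n_targets) %in% embed_idx,
                          position = pos, stringsAsFactors = FALSE))
}
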