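#' Dicodon shuffle of a coding sequence
#'
#' Randomizes codon order under three exact constraints: the encoded
#' protein, the codon multiset (codon usage) and all 16 dinucleotide
#' counts of the full sequence are preserved. The sampler is a Markov
#' chain of codon swaps between positions encoding the same amino
#' acid; a proposed swap is accepted only when the multiset of codon
#' junction dinucleotides it touches is unchanged (codon-internal
#' dinucleotides travel with their codon), so the invariants hold
#' exactly for every output. The first codon is held fixed and the
#' stop codon takes part in the shuffled region. A sequence with no
#' admissible rearrangement is returned unchanged.
#'
#' Randomness is drawn from R's RNG: call `set.seed()` (or use
#' [randomize_genome()]) for reproducibility.
#'
#' @param cds valid coding sequence (see [validate_cds()]).
#' @param sweeps_mult number of attempted swaps per codon; the default
#'   10 gives `10 * n_codons` attempts.
#' @return shuffled CDS string.
#' @export
dicodon_shuffle <- function(cds, sweeps_mult = 10) {
  validate_cds(cds)
  .shuffle_codons_cpp(cds, sweeps_mult)
}

#' Independent dicodon-shuffled replicates of a genome
#'
#' Every gene is shuffled independently within each replicate, and
#' replicate `r` is reproducible from `(seed, r)` alone. When `FUN` is
#' supplied it is applied to each replicate genome and only its results
#' are kept (used by [null_frequency_summary()] to stream moments
#' instead of storing full genomes).
#'
#' @param genome named character vector of valid CDSs.
#' @param n_replicates number of randomized genomes.
#' @param seed master seed.
#' @param sweeps_mult see [dicodon_shuffle()].
#' @param FUN optional function applied to each replicate genome.
#' @return list of length `n_replicates`: replicate genomes, or `FUN`
#'   results.
#' @export
randomize_genome <- function(genome, n_replicates, seed, sweeps_mult = 10,
                             FUN = NULL) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    set.seed(replicate_seed(seed, r))
    shuffled <- vapply(genome, .shuffle_codons_cpp, character(1),
                       sweeps_mult = sweeps_mult)
    if (is.null(FUN)) shuffled else FUN(shuffled)
  })
}

#' Null distribution of motif counts under dicodon shuffling
#'
#' Streams per-(pattern, phase) count moments over `n_replicates`
#' randomized genomes; replicate genomes are not retained unless
#' `keep_replicates = TRUE` (needed for medians/quantiles, e.g. violin
#' exports).
#'
#' @inheritParams randomize_genome
#' @param patterns equal-length motif literals.
#' @param keep_replicates keep the full replicate count matrix.
#' @return data.frame with columns `pattern`, `phase`, `x_mean`,
#'   `x_sd` (and `median`, `q1`, `q3`, `lo95`, `hi95` when replicates
#'   are kept); attribute `n_replicates`, and `replicates` (a matrix
#'   of per-cell counts) when kept.
#' @export
null_frequency_summary <- function(genome, patterns = enumerate_heptamers(),
                                   n_replicates = 1000, seed = 1,
                                   sweeps_mult = 10, keep_replicates = FALSE) {
  patterns <- sort(patterns)
  np <- length(patterns)
  s1 <- matrix(0, np, 3)
  s2 <- matrix(0, np, 3)
  reps <- if (keep_replicates) matrix(0L, np * 3L, n_replicates) else NULL
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    m <- .shuffled_counts_cpp(unname(genome), patterns, sweeps_mult)
    s1 <- s1 + m
    s2 <- s2 + m * m
    if (keep_replicates) reps[, r] <- as.integer(m)
  }
  mean_ <- s1 / n_replicates
  var_ <- (s2 - n_replicates * mean_ * mean_) / max(1, n_replicates - 1)
  var_[var_ < 0] <- 0  # numerical guard
  out <- data.frame(pattern = rep(patterns, times = 3),
                    phase = rep(0:2, each = np),
                    x_mean = as.vector(mean_),
                    x_sd = sqrt(as.vector(var_)),
                    stringsAsFactors = FALSE)
  if (keep_replicates) {
    qs <- t(apply(reps, 1, stats::quantile,
                  probs = c(0.5, 0.25, 0.75, 0.025, 0.975), names = FALSE))
    out$median <- qs[, 1]; out$q1 <- qs[, 2]; out$q3 <- qs[, 3]
    out$lo95 <- qs[, 4]; out$hi95 <- qs[, 5]
  }
  out <- out[order(out$pattern, out$phase), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_replicates") <- n_replicates
  if (keep_replicates) {
    rownames(reps) <- paste(rep(patterns, times = 3),
                            rep(0:2, each = np))
    attr(out, "replicates") <- reps
  }
  out
}

#' Per-pattern z-scores against the shuffling null
#'
#' `z = (x - x_mean) / x_sd`, where `x` is the observed genome count of
#' a (pattern, phase) cell and the moments come from the randomized
#' genomes. A negative z-score marks under-representation. Cells with
#' `x_sd == 0` are flagged undefined (`z = NA`) and are excluded from
#' downstream correlations.
#'
#' @param observed frequency table from [count_motif_frequencies()].
#' @param null null summary from [null_frequency_summary()].
#' @return data.frame with columns `pattern`, `phase`, `x`, `x_mean`,
#'   `x_sd`, `z`, `undefined`.
#' @export
compute_zscores <- function(observed, null) {
  key_obs <- paste(observed$pattern, observed$phase)
  key_null <- paste(null$pattern, null$phase)
  if (!setequal(key_obs, key_null))
    stop("observed and null tables must cover the same (pattern, phase) cells")
  idx <- match(key_obs, key_null)
  out <- data.frame(pattern = observed$pattern, phase = observed$phase,
                    x = observed$count,
                    x_mean = null$x_mean[idx], x_sd = null$x_sd[idx],
                    stringsAsFactors = FALSE)
  out$undefined <- out$x_sd == 0
  out$z <- ifelse(out$undefined, NA_real_, (out$x - out$x_mean) / out$x_sd)
  out[order(out$pattern, out$phase), , drop = FALSE]
}

#' Correlation between z-scores and frameshift efficiencies
#'
#' Pearson correlation over the patterns shared by a z-score table and
#' an efficiency map, with a two-sided p-value from the t distribution
#' on n - 2 degrees of freedom. Undefined z-scores are dropped.
#'
#' @param zscores data.frame from [compute_zscores()], usually
#'   restricted to phase 2.
#' @param efficiency named numeric vector, percent frameshifting per
#'   pattern.
#' @return list with `r`, `p`, `n`.
#' @export
efficiency_zscore_correlation <- function(zscores, efficiency) {
  z <- zscores[!is.na(zscores$z) & zscores$pattern %in% names(efficiency), ]
  if (nrow(z) < 3) stop("need at least 3 shared patterns")
  e <- efficiency[z$pattern]
  if (sd(z$z) == 0 || sd(e) == 0)
    stop("zero variance in z-scores or efficiencies")
  ct <- cor.test(z$z, e, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(z))
}

#' Select candidate slippery motifs
#'
#' Selects heptamers that are under-represented in the shifty phase
#' (`z < z_max`) and frameshift-competent in vivo (`efficiency >
#' eff_min`, percent without stimulator), then adds any manually
#' nominated high-efficiency patterns. With published-style inputs the
#' base rule yields 18 patterns and three manual additions give 21.
#'
#' @param zscores z-score table covering all 64 heptamers at phase 2
#'   (rows at other phases are ignored).
#' @param efficiency named percent-frameshifting map for all 64
#'   heptamers.
#' @param z_max exclusive upper bound on z (default 0).
#' @param eff_min exclusive lower bound on efficiency, percent
#'   (default 0.10).
#' @param manual_add patterns added regardless of the rule.
#' @return sorted character vector of selected patterns, with the rule-
#'   based subset in attribute `"base_set"`.
#' @export
select_candidate_motifs <- function(zscores, efficiency, z_max = 0,
                                    eff_min = 0.10, manual_add = character()) {
  z2 <- zscores[zscores$phase == 2L, , drop = FALSE]
  hepts <- enumerate_heptamers()
  missing_z <- setdiff(hepts, z2$pattern)
  missing_e <- setdiff(hepts, names(efficiency))
  if (length(missing_z) || length(missing_e))
    stop("missing pattern rows: ",
         paste(head(union(missing_z, missing_e), 8), collapse = ", "))
  z <- setNames(z2$z, z2$pattern)[hepts]
  eff <- efficiency[hepts]
  base <- hepts[!is.na(z) & z < z_max & eff > eff_min]
  out <- sort(union(base, manual_add))
  attr(out, "base_set") <- sort(base)
  out
}
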