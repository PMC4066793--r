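#' Mean per-column divergence of an alignment
#'
#' A star-phylogeny approximation to the mean number of independent
#' substitutions per alignment column: each column that is not
#' gap-majority contributes the number of distinct residues observed
#' (gaps excluded) minus one, and the statistic is the mean over those
#' columns. Identical rows give 0; the value grows with divergence but
#' ignores phylogenetic structure, so shared ancestry inflates it
#' relative to a tree-aware count.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @return non-negative scalar.
#' @export
aln_div <- function(aln) {
  if (length(unique(nchar(aln))) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(aln, ""))
  vals <- apply(mat, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) return(NA_real_)
    res <- unique(col[col != "-"])
    max(0L, length(res) - 1L)
  })
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

#' Synonymous-site conservation profile over a codon alignment
#'
#' A simplified sliding-window statistic for reduced synonymous-site
#' variability (RSSV): per codon column, member codons that encode the
#' same amino acid as the reference are synonymous opportunities, and
#' those that differ in sequence while staying synonymous count as
#' observed synonymous changes (columns where a member's amino acid
#' differs from the reference are excluded from that member's
#' opportunities). The alignment-wide synonymous-change rate gives the
#' expected count per window, and each sliding window of
#' `window` codons gets a one-sided binomial tail probability
#' `P(X <= observed)`; windows with `p < alpha` are flagged as showing
#' reduced variability. This is a homogeneous-rate desk statistic, not
#' a phylogenetic method: shared ancestry among members is ignored.
#'
#' @param codon_aln named character vector of gapped CDS rows whose
#'   gaps respect codon boundaries (every row is a sequence of codons
#'   and `---` blocks).
#' @param reference id of the reference row.
#' @param window window length in codons (default 15).
#' @param alpha flag threshold on the binomial tail.
#' @return data.frame with one row per window: `window_start_codon`
#'   (0-based), `observed`, `opportunities`, `expected`, `p`,
#'   `reduced`; attribute `"rate"` holds the alignment-wide rate.
#' @export
syn_conservation_profile <- function(codon_aln, reference, window = 15,
                                     alpha = 0.05) {
  if (!reference %in% names(codon_aln))
    stop("reference row '", reference, "' not in alignment")
  if (length(unique(nchar(codon_aln))) != 1)
    stop("alignment rows differ in length")
  width <- unique(nchar(codon_aln))
  if (width %% 3 != 0) stop("alignment width is not a multiple of 3")
  n_col <- width %/% 3
  codon_rows <- lapply(codon_aln, function(row) {
    codons <- substring(row, seq(1, width, 3), seq(3, width, 3))
    bad <- grepl("-", codons) & codons != "---"
    if (any(bad))
      stop("row has gaps that do not respect codon boundaries ",
           "(frameshifted row?)")
    codons
  })
  code <- Biostrings::getGeneticCode("11")
  aa_of <- function(codon) if (codon == "---") NA_character_ else
    unname(code[codon])
  ref_codons <- codon_rows[[reference]]
  members <- setdiff(names(codon_aln), reference)

  obs <- integer(n_col)
  opp <- integer(n_col)
  for (id in members) {
    mc <- codon_rows[[id]]
    for (j in seq_len(n_col)) {
      if (ref_codons[j] == "---" || mc[j] == "---") next
      aa_r <- aa_of(ref_codons[j]); aa_m <- aa_of(mc[j])
      if (is.na(aa_r) || is.na(aa_m) || aa_r != aa_m) next
      opp[j] <- opp[j] + 1L
      if (mc[j] != ref_codons[j]) obs[j] <- obs[j] + 1L
    }
  }
  tot_opp <- sum(opp)
  rate <- if (tot_opp > 0) sum(obs) / tot_opp else 0

  n_win <- max(0L, n_col - window + 1L)
  out <- do.call(rbind, lapply(seq_len(n_win), function(s) {
    idx <- s:(s + window - 1L)
    o <- sum(obs[idx]); k <- sum(opp[idx])
    p <- if (k > 0 && rate > 0) pbinom(o, k, rate) else 1
    data.frame(window_start_codon = s - 1L, observed = o,
               opportunities = k, expected = k * rate, p = p,
               reduced = k > 0 && p < alpha)
  }))
  if (is.null(out))
    out <- data.frame(window_start_codon = integer(), observed = integer(),
                      opportunities = integer(), expected = numeric(),
                      p = numeric(), reduced = logical())
  attr(out, "rate") <- rate
  out
}
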