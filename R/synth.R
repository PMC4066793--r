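#' Default codon usage table (E. coli K-12 style)
#'
#' Per-thousand codon frequencies typical of *Escherichia coli* K-12
#' coding sequences, used as the default codon-usage model of the
#' synthetic-genome generator.
#'
#' @return named numeric vector over all 64 codons (per-thousand).
#' @export
ecoli_codon_usage <- function() {
  c(TTT = 22.2, TTC = 16.6, TTA = 13.9, TTG = 13.7,
    CTT = 11.0, CTC = 11.0, CTA = 3.9,  CTG = 52.9,
    ATT = 30.4, ATC = 25.1, ATA = 4.4,  ATG = 27.9,
    GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4,
    TCT = 8.5,  TCC = 8.6,  TCA = 7.2,  TCG = 8.9,
    CCT = 7.0,  CCC = 5.5,  CCA = 8.4,  CCG = 23.2,
    ACT = 9.0,  ACC = 23.4, ACA = 7.1,  ACG = 14.4,
    GCT = 15.3, GCC = 25.5, GCA = 20.1, GCG = 33.6,
    TAT = 16.2, TAC = 12.2, TAA = 2.0,  TAG = 0.2,
    CAT = 12.9, CAC = 9.7,  CAA = 15.3, CAG = 28.8,
    AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
    GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8,
    TGT = 5.2,  TGC = 6.4,  TGA = 1.0,  TGG = 15.2,
    CGT = 20.9, CGC = 22.0, CGA = 3.6,  CGG = 5.4,
    AGT = 8.8,  AGC = 16.1, AGA = 2.1,  AGG = 1.2,
    GGT = 24.7, GGC = 29.6, GGA = 8.0,  GGG = 11.1)
}

all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

# synonymous alternatives (same amino acid, different codon)
synonym_table <- function() {
  code <- Biostrings::getGeneticCode("11")
  lapply(setNames(nm = all_codons()), function(cd) {
    aa <- unname(code[cd])
    setdiff(names(code)[code == aa], cd)
  })
}

# one random gene body: start codon + internal sense codons + stop
sample_gene <- function(n_codons, usage) {
  sense <- sense_codons()
  p_sense <- usage[sense] / sum(usage[sense])
  p_stop <- usage[STOP_CODONS] / sum(usage[STOP_CODONS])
  internal <- sample(sense, n_codons - 2L, replace = TRUE, prob = p_sense)
  paste0("ATG", paste(internal, collapse = ""),
         sample(STOP_CODONS, 1L, prob = p_stop))
}

#' Generate a synthetic genome of coding sequences
#'
#' Genes are sampled codon by codon from a codon-usage table
#' (start codon `ATG`, internal sense codons, weighted stop), with
#' gene lengths drawn from a gamma distribution. With
#' `dinuc_bias > 0`, each internal codon is instead drawn sequentially
#' with probabilities reweighted by a target junction-dinucleotide
#' weight matrix (the strength parameter interpolates between
#' independent codons and the target), which gives the shuffling null
#' a non-trivial dinucleotide structure to preserve. Output is
#' byte-deterministic per seed, and every gene validates as a CDS.
#'
#' @param n_genes number of genes.
#' @param mean_codons,min_codons gene-length distribution (codons,
#'   start and stop included).
#' @param codon_usage named per-thousand (or any relative) weights
#'   over all 64 codons.
#' @param dinuc_bias junction-dinucleotide bias strength in `[0, 1]`.
#' @param dinuc_target 4x4 weight matrix (rows: previous base, cols:
#'   next base); defaults to a mild CG/TA-depleted profile.
#' @param seed RNG seed.
#' @return named character vector of CDSs.
#' @export
gen_genome <- function(n_genes = 2000, mean_codons = 250, min_codons = 60,
                       codon_usage = ecoli_codon_usage(), dinuc_bias = 0,
                       dinuc_target = NULL, seed = 1) {
  stopifnot(dinuc_bias >= 0, dinuc_bias <= 1)
  set.seed(seed)
  lens <- pmax(min_codons,
               round(rgamma(n_genes, shape = 3, rate = 3 / mean_codons)))
  sense <- sense_codons()
  p_sense <- codon_usage[sense] / sum(codon_usage[sense])
  p_stop <- codon_usage[STOP_CODONS] / sum(codon_usage[STOP_CODONS])
  if (dinuc_bias == 0) {
    total <- sum(lens - 2L)
    pool <- sample(sense, total, replace = TRUE, prob = p_sense)
    idx <- rep.int(seq_len(n_genes), lens - 2L)
    bodies <- vapply(split(pool, idx), paste, character(1), collapse = "")
    stops <- sample(STOP_CODONS, n_genes, replace = TRUE, prob = p_stop)
    genes <- paste0("ATG", bodies, stops)
  } else {
    if (is.null(dinuc_target)) {
      dinuc_target <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
      dinuc_target["C", "G"] <- 0.5
      dinuc_target["T", "A"] <- 0.6
      dinuc_target["G", "C"] <- 1.3
    }
    first_base <- substr(sense, 1, 1)
    genes <- vapply(lens, function(len) {
      codons <- character(len - 2L)
      prev <- "G"  # last base of ATG
      for (i in seq_len(len - 2L)) {
        w <- p_sense * (1 - dinuc_bias +
                          dinuc_bias * dinuc_target[prev, first_base])
        cd <- sample(sense, 1L, prob = w / sum(w))
        codons[i] <- cd
        prev <- substr(cd, 3, 3)
      }
      paste0("ATG", paste(codons, collapse = ""),
             sample(STOP_CODONS, 1L, prob = p_stop))
    }, character(1))
  }
  setNames(genes, sprintf("g%05d", seq_len(n_genes)))
}

#' Deplete occurrences of a motif by synonymous re-coding
#'
#' Removes a fraction of the phase-matched occurrences of a pattern by
#' replacing one of the codons it overlaps with a synonymous codon
#' that breaks the literal. The encoded proteins are untouched; used
#' to plant an under-representation signal for z-score recovery tests.
#'
#' @param genome named character vector of valid CDSs.
#' @param pattern motif literal.
#' @param phase phase of the targeted occurrences (2 = shifty).
#' @param fraction fraction of occurrences to remove; 1 iterates until
#'   none remain (or none are breakable).
#' @param seed RNG seed.
#' @return the modified genome, with attributes `n_initial` and
#'   `n_remaining` (phase-matched occurrence counts).
#' @export
deplete_pattern <- function(genome, pattern, phase = 2, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  syn <- synonym_table()
  k <- nchar(pattern)

  break_hit <- function(seq, s) {  # s: 0-based hit start
    ci <- (s %/% 3L):((s + k - 1L) %/% 3L)
    ci <- ci[ci > 0L]  # keep the start codon intact
    for (i in sample(ci)) {
      current <- substr(seq, 3L * i + 1L, 3L * i + 3L)
      alts <- syn[[current]]
      if (!length(alts)) next
      for (alt in sample(alts)) {
        cand <- seq
        substr(cand, 3L * i + 1L, 3L * i + 3L) <- alt
        if (substr(cand, s + 1L, s + k) != pattern) return(cand)
      }
    }
    seq
  }

  hits_of <- function(seq) {
    h <- scan_motifs(seq, pattern)
    h$start[h$phase == phase]
  }

  all_hits <- lapply(genome, hits_of)
  n_initial <- sum(lengths(all_hits))
  n_break <- round(fraction * n_initial)
  if (n_break > 0 && n_initial > 0) {
    flat <- data.frame(
      gene = rep(names(genome), lengths(all_hits)),
      start = unlist(all_hits, use.names = FALSE))
    chosen <- flat[sample(nrow(flat), n_break), , drop = FALSE]
    for (g in unique(chosen$gene)) {
      seq <- genome[[g]]
      for (s in chosen$start[chosen$gene == g]) {
        if (substr(seq, s + 1L, s + k) == pattern) seq <- break_hit(seq, s)
      }
      genome[[g]] <- seq
    }
    if (fraction == 1) {
      for (iter in 1:20) {
        remaining <- lapply(genome, hits_of)
        if (sum(lengths(remaining)) == 0) break
        changed <- FALSE
        for (g in names(genome)) {
          seq <- genome[[g]]
          for (s in remaining[[g]]) {
            new <- break_hit(seq, s)
            if (new != seq) { seq <- new; changed <- TRUE }
          }
          genome[[g]] <- seq
        }
        if (!changed) break
      }
    }
  }
  attr(genome, "n_initial") <- n_initial
  attr(genome, "n_remaining") <-
    sum(lengths(lapply(genome, hits_of)))
  genome
}

#' Generate a gene cluster with a planted slippery motif
#'
#' Builds a parent CDS carrying the motif in the shifty phase (its
#' first base on the last position of a codon) and derives members by
#' per-site substitution at a given rate. The motif window is masked
#' from mutation when `conserve_motif`; internal codons that a
#' mutation would turn into stops are reverted. Optionally the last
#' `n_jitter` members carry the motif displaced by a whole number of
#' codons (so it stays in phase but off the conserved site, landing in
#' the 36-nt window category). Members are equal-length with no
#' indels, so the gap-free alignment is the members themselves and the
#' conserved alignment column equals the motif start.
#'
#' @param n_members cluster size.
#' @param n_codons gene length in codons.
#' @param motif heptamer literal to plant.
#' @param motif_codon 0-based index of the codon whose last base is
#'   the motif start.
#' @param sub_rate per-site substitution probability per member.
#' @param conserve_motif mask the motif site from mutation.
#' @param n_jitter number of members with a displaced motif.
#' @param jitter_codons maximum displacement in codons (displacement
#'   is a uniform nonzero draw from `-jitter_codons..jitter_codons`).
#' @param codon_usage usage table for the parent gene.
#' @param seed RNG seed.
#' @return list with `members` (named character vector), `parent`,
#'   `motif`, `motif_start` (0-based), `conserved_column` (same, the
#'   alignment is gap-free) and `labels` (true per-member
#'   N-categories, determined by direct inspection of each member).
#' @export
gen_cluster <- function(n_members = 25, n_codons = 200, motif = "AAAAAAG",
                        motif_codon = round(n_codons / 2), sub_rate = 0.02,
                        conserve_motif = TRUE, n_jitter = 0,
                        jitter_codons = 3, codon_usage = ecoli_codon_usage(),
                        seed = 1) {
  stopifnot(motif %in% enumerate_heptamers(),
            motif_codon >= 1, motif_codon + 2 < n_codons - 1)
  set.seed(seed)
  parent <- sample_gene(n_codons, codon_usage)

  plant <- function(seq, i) {
    # codon i ends with X (GCx = Ala keeps the frame stop-free), then
    # codons XXZ and ZZN complete the heptamer at s = 3 i + 2
    x <- substr(motif, 1, 1)
    substr(seq, 3 * i + 1, 3 * i + 3) <- paste0("GC", x)
    substr(seq, 3 * i + 4, 3 * i + 6) <- substr(motif, 2, 4)
    substr(seq, 3 * i + 7, 3 * i + 9) <- substr(motif, 5, 7)
    seq
  }
  unplant <- function(seq, i) {
    substr(seq, 3 * i + 4, 3 * i + 6) <- "GCT"  # Ala, breaks XXZ run
    seq
  }
  parent <- plant(parent, motif_codon)
  s <- 3L * motif_codon + 2L

  mutate <- function(seq, protect) {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    idx <- which(runif(n) < sub_rate)
    idx <- setdiff(idx, c(1:3, protect))
    for (p in idx) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    out <- paste(chars, collapse = "")
    # revert internal codons that became stops
    for (j in seq_len(n / 3 - 2)) {
      cd <- substr(out, 3 * j + 1, 3 * j + 3)
      if (cd %in% STOP_CODONS)
        substr(out, 3 * j + 1, 3 * j + 3) <- substr(seq, 3 * j + 1, 3 * j + 3)
    }
    out
  }

  members <- character(n_members)
  for (m in seq_len(n_members)) {
    jittered <- m > n_members - n_jitter
    base <- parent
    delta <- 0L
    if (jittered) {
      delta <- sample(setdiff(-jitter_codons:jitter_codons, 0L), 1L)
      base <- plant(unplant(base, motif_codon), motif_codon + delta)
    }
    site <- 3L * (motif_codon + delta) + 2L
    protect <- if (conserve_motif) (site + 1L):(site + 7L) else integer()
    members[m] <- mutate(base, protect)
  }
  names(members) <- sprintf("m%03d", seq_len(n_members))

  hepts <- enumerate_heptamers()
  labels <- vapply(members, function(seq) {
    at <- substr(seq, s + 1L, s + 7L)
    if (at == motif) return("N1")
    if (at %in% hepts) return("N2")
    ws <- max(0L, s - 15L)
    window <- substr(seq, ws + 1L, min(nchar(seq), ws + 36L))
    if (nrow(scan_motifs(window, hepts)) > 0) "N3" else "none"
  }, character(1))

  list(members = members, parent = parent, motif = motif,
       motif_start = s, conserved_column = s, labels = labels)
}

#' Plant stimulator elements around a motif
#'
#' Overwrites a designed upstream segment with an SD-like match at a
#' requested spacing and/or a downstream inverted repeat forming a
#' stem-loop hairpin at a requested distance. Sequence length and
#' reading frame are untouched (substitution only); the fixtures are
#' meant for stimulator scanning, not for translation-faithful use.
#'
#' @param cds DNA sequence containing the motif.
#' @param motif_start 0-based motif start.
#' @param motif_len motif length.
#' @param sd_pattern SD literal to plant (`NULL` to skip).
#' @param sd_spacing spacing under the [scan_sd()] convention.
#' @param stem_bp hairpin stem length in base pairs (`NULL` to skip);
#'   the stem is GC-rich with a G-C outermost pair.
#' @param loop loop sequence.
#' @param hairpin_distance nt between the motif's last base and the
#'   first paired base (4 means immediately at the segment start).
#' @param seed RNG seed for the stem sequence.
#' @return modified sequence.
#' @export
plant_stimulators <- function(cds, motif_start, motif_len = 7L,
                              sd_pattern = "GGAG", sd_spacing = 10L,
                              stem_bp = 12L, loop = "GAAA",
                              hairpin_distance = 5L, seed = 1) {
  set.seed(seed)
  if (!is.null(sd_pattern)) {
    sd_end <- motif_start + 1L - sd_spacing  # 0-based exclusive
    sd_start <- sd_end - nchar(sd_pattern)
    if (sd_start < 0) stop("SD does not fit upstream of the motif")
    substr(cds, sd_start + 1L, sd_end) <- sd_pattern
  }
  if (!is.null(stem_bp)) {
    stem <- paste0("G", paste(sample(DNA_BASES, stem_bp - 1L, replace = TRUE,
                                     prob = c(0.15, 0.35, 0.35, 0.15)),
                              collapse = ""))
    hairpin <- paste0(stem, loop, revcomp(stem))
    g <- segment_start0(motif_start, motif_len)
    o <- hairpin_distance - 4L
    if (o < 0) stop("hairpin distance must be at least 4")
    hp_start <- g + o
    if (hp_start + nchar(hairpin) > nchar(cds))
      stop("hairpin does not fit downstream of the motif")
    substr(cds, hp_start + 1L, hp_start + nchar(hairpin)) <- hairpin
  }
  cds
}

#' Generate a noisy reporter-assay table from planted truth
#'
#' Produces a long-format assay table (one row per replicate) from a
#' truth table of per-construct frameshift percentages. Activities are
#' the reference activity scaled by the true percentage with
#' multiplicative log-normal noise of coefficient of variation `cv`;
#' `cv = 0` recovers the planted percentages exactly.
#'
#' @param truth data.frame with columns `motif`, `context`, `percent`
#'   and `control_percent` (`NA` drops the per-motif control
#'   construct, as for contexts whose background is a context-wide
#'   scalar).
#' @param cv replicate coefficient of variation.
#' @param n_replicates replicates per construct (reference included).
#' @param reference_activity activity of the in-frame reference.
#' @param seed RNG seed.
#' @return data.frame with columns `construct_id`, `context`, `motif`,
#'   `role`, `replicate`, `activity`.
#' @export
gen_assay_table <- function(truth, cv = 0.05, n_replicates = 5,
                            reference_activity = 10000, seed = 1) {
  set.seed(seed)
  noisy <- function(target, n) {
    if (cv == 0) rep(target, n)
    else target * rlnorm(n, meanlog = -cv^2 / 2, sdlog = cv)
  }
  rows <- list()
  emit <- function(context, motif, role, target) {
    act <- noisy(target, n_replicates)
    rows[[length(rows) + 1L]] <<- data.frame(
      construct_id = paste(context, if (is.na(motif)) "ref" else motif,
                           role, sep = "_"),
      context = context, motif = motif, role = role,
      replicate = seq_len(n_replicates), activity = act,
      stringsAsFactors = FALSE)
  }
  for (ctx in unique(truth$context)) {
    emit(ctx, NA_character_, "reference", reference_activity)
    sub <- truth[truth$context == ctx, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      emit(ctx, sub$motif[i], "motif",
           reference_activity * sub$percent[i] / 100)
      if (!is.na(sub$control_percent[i]))
        emit(ctx, sub$motif[i], "control",
             reference_activity * sub$control_percent[i] / 100)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------
# Synthetic counterparts of the published per-motif summary tables.
# The marginal structure (which motifs are frameshift-prone in each
# stimulator context, which are under-represented, and which clear the
# selection rule) is planted; per-motif magnitudes are spread over
# realistic ranges following a mechanistic shiftiness ranking.
# ---------------------------------------------------------------------

# qualitative shiftiness of a heptamer XXXZZZN: re-pairing is easiest
# when the A-site codon ZZN starts with a weakly pairing base (A/T),
# when ZZN and the X/Z pair are homogeneous (all-purine or
# all-pyrimidine), and when ZZN is AAG (lysyl-tRNA slipperiness)
motif_shiftiness_score <- function(motif) {
  x <- substr(motif, 1, 1); z <- substr(motif, 4, 4); n <- substr(motif, 7, 7)
  s <- 0
  if (z %in% c("A", "T")) s <- s + 3
  if (is_purine(z) == is_purine(n)) s <- s + 2
  if (is_purine(x) == is_purine(z)) s <- s + 1
  if (z == "A" && n == "G") s <- s + 1.5
  if (!is_purine(x) && z == "A" && is_purine(n)) s <- s + 1    # YYA.AAR
  if (is_purine(x) && z == "T" && !is_purine(n)) s <- s + 1    # RRU.UUY
  s
}

# the 18 heptamers that are both under-represented in the shifty phase
# and frameshift-competent without stimulators, plus the 3 additional
# high-efficiency patterns nominated by hand (DNA alphabet)
underrepresented_efficient_heptamers <- function() {
  c("AAAAAAA", "AAAAAAG", "AAAAAAC", "AAAGGGC", "AAAGGGT", "CCCAAAA",
    "CCCAAAG", "CCCCCCA", "CCCCCCG", "CCCTTTA", "CCCTTTG", "CCCTTTT",
    "GGGAAAG", "TTTAAAG", "TTTAAAT", "TTTCCCA", "TTTTTTC", "TTTTTTT")
}

manual_candidate_heptamers <- function() c("CCCTTTC", "AAAGGGA", "AAAGGGG")

is3_nonresponsive_heptamers <- function() c("AAACCCA", "GGGCCCA", "CCCGGGC")

#' Planted per-motif truth for the three assay contexts
#'
#' Builds the true frameshift percentages of all 64 heptamers in the
#' three reporter contexts (no stimulator, the moderate SD+hairpin
#' combination, and the strong downstream pseudoknot). The planted
#' margins are: 39 motifs prone (ratio > 2 over their non-shifty
#' control) without stimulator, 55 with the moderate stimulators, and
#' all but three named motifs with the strong pseudoknot; the
#' best motif (`CCCAAAG`) tops every context, reaching 54% with the
#' pseudoknot, and the 21 selection-rule patterns all exceed 0.10%
#' without stimulator. Background (control) levels are 0.055%,
#' 0.037% and 0.069% respectively; the pseudoknot context has no
#' per-motif controls (its background enters as a scalar).
#'
#' @return data.frame with columns `motif`, `context`, `percent`,
#'   `control_percent`; attributes `prone` (list of per-context motif
#'   sets) and `selection` (list with `base18`, `manual3`,
#'   `is3_failures`).
#' @export
synthetic_assay_truth <- function() {
  hepts <- enumerate_heptamers()
  c18 <- underrepresented_efficient_heptamers()
  m3 <- manual_candidate_heptamers()
  fails <- is3_nonresponsive_heptamers()
  c21 <- c(c18, m3)
  score <- vapply(hepts, motif_shiftiness_score, numeric(1))
  ranked <- hepts[order(-score, hepts)]
  # motifs never promoted by rank: the pseudoknot non-responders, the
  # weakest assayed motif, and the over-represented codon-pair motif
  excluded <- c(fails, "GGGGGGT", "TTTCCCG")

  fill <- function(already, n_extra) {
    pool <- setdiff(ranked, c(already, excluded))
    pool[seq_len(n_extra)]
  }
  prone_none <- c(c21, fill(c21, 39 - length(c21)))
  prone_is911 <- c(prone_none, fill(prone_none, 55 - length(prone_none)))
  prone_is3 <- setdiff(hepts, fails)

  rank_order <- function(set) {
    rest <- setdiff(set, "CCCAAAG")
    rest <- rest[order(-score[match(rest, hepts)], rest)]
    if ("CCCAAAG" %in% set) c("CCCAAAG", rest) else rest
  }
  spread <- function(set, hi, lo) {
    ord <- rank_order(set)
    setNames(seq(hi, lo, length.out = length(ord)), ord)
  }

  eff_none <- setNames(numeric(64), hepts)
  eff_none[prone_none] <- spread(prone_none, 0.55, 0.14)
  np_none <- setdiff(hepts, prone_none)
  eff_none[np_none] <- seq(0.085, 0.018,
                           length.out = length(np_none))[
                             rank(-score[match(np_none, hepts)],
                                  ties.method = "first")]
  eff_none["GGGGGGT"] <- 0.018

  eff_is911 <- setNames(numeric(64), hepts)
  eff_is911[prone_is911] <- spread(prone_is911, 4.1, 0.10)
  np_911 <- setdiff(hepts, prone_is911)
  eff_is911[np_911] <- seq(0.058, 0.020, length.out = length(np_911))

  eff_is3 <- setNames(numeric(64), hepts)
  eff_is3[prone_is3] <- spread(prone_is3, 54, 0.26)
  eff_is3[fails] <- 0.10

  truth <- rbind(
    data.frame(motif = hepts, context = "none", percent = eff_none[hepts],
               control_percent = 0.055, stringsAsFactors = FALSE),
    data.frame(motif = hepts, context = "IS911", percent = eff_is911[hepts],
               control_percent = 0.037, stringsAsFactors = FALSE),
    data.frame(motif = hepts, context = "IS3", percent = eff_is3[hepts],
               control_percent = NA_real_, stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  attr(truth, "prone") <- list(none = sort(prone_none),
                               IS911 = sort(prone_is911),
                               IS3 = sort(prone_is3))
  attr(truth, "selection") <- list(base18 = sort(c18), manual3 = m3,
                                   is3_failures = fails)
  attr(truth, "background") <- c(none = 0.055, IS911 = 0.037, IS3 = 0.069)
  truth
}

#' Synthetic z-score table for the 64 heptamers in three phases
#'
#' Emulates a genome-scale under-representation survey: in the shifty
#' phase, exactly the 18 selection-rule patterns are under-represented
#' among the frameshift-competent motifs; most low-efficiency motifs
#' are also under-represented (42/64 negative overall), the
#' homopolymeric `AAAAAAA`/`TTTTTTT` are strongly depleted in all
#' three phases, and the codon-pair-favoured `TTTCCCG` is
#' over-represented. Counts `x`, `x_mean` and `x_sd` are generated
#' consistently with each planted z (so `z == (x - x_mean) / x_sd`
#' holds exactly after rounding `x` to an integer).
#'
#' @param seed RNG seed for the magnitudes.
#' @return data.frame shaped like [compute_zscores()] output.
#' @export
synthetic_zscore_table <- function(seed = 1) {
  set.seed(seed)
  hepts <- enumerate_heptamers()
  truth <- synthetic_assay_truth()
  sel <- attr(truth, "selection")
  prone_none <- attr(truth, "prone")$none
  c18 <- sel$base18

  z2 <- setNames(numeric(64), hepts)
  z2[c18] <- seq(-4.5, -1.2, length.out = 18)
  z2["AAAAAAA"] <- -6.0
  z2["TTTTTTT"] <- -5.5
  other_prone <- setdiff(prone_none, c18)
  z2[other_prone] <- seq(0.3, 2.0, length.out = length(other_prone))
  np <- setdiff(hepts, c(prone_none, "TTTCCCG"))
  z2[np] <- seq(-3.0, -0.4, length.out = length(np))
  z2["TTTCCCG"] <- 3.5

  rows <- lapply(0:2, function(ph) {
    z <- if (ph == 2) z2 else {
      zz <- setNames(runif(64, -1.4, 1.4), hepts)
      zz["AAAAAAA"] <- runif(1, -5.5, -4.0)
      zz["TTTTTTT"] <- runif(1, -5.0, -3.5)
      zz
    }
    x_mean <- runif(64, 150, 3000)
    x_sd <- sqrt(x_mean) * runif(64, 0.8, 1.2)
    x <- pmax(0, round(x_mean + z * x_sd))
    data.frame(pattern = hepts, phase = ph, x = x, x_mean = x_mean,
               x_sd = x_sd, z = (x - x_mean) / x_sd, undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pattern, out$phase), , drop = FALSE]
  rownames(out) <- NULL
  out
}
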