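#' The slippery-motif universe
#'
#' [enumerate_heptamers()] returns the 64 heptamer slippery motifs
#' `XXXZZZN` (two runs of three identical bases followed by any base);
#' [enumerate_tetramers()] returns the 16 tetramer motifs `ZZZN`. In
#' frame notation the heptamer is written `X_XXZ_ZZN`: the first base is
#' the last base of a frame-0 codon, so the biologically shifty
#' configuration has phase 2 (0-based start modulo 3).
#'
#' @return character vector of motif literals, lexicographically sorted.
#' @export
enumerate_heptamers <- function() {
  g <- expand.grid(N = DNA_BASES, Z = DNA_BASES, X = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$X, g$X, g$X, g$Z, g$Z, g$Z, g$N))
}

#' @rdname enumerate_heptamers
#' @export
enumerate_tetramers <- function() {
  g <- expand.grid(N = DNA_BASES, Z = DNA_BASES, stringsAsFactors = FALSE)
  sort(paste0(g$Z, g$Z, g$Z, g$N))
}

#' Scan a sequence for exact motif occurrences
#'
#' Reports every exact, possibly overlapping, occurrence of each
#' pattern, with its 0-based start and phase (`start %% 3`).
#'
#' @param seq single DNA string.
#' @param patterns character vector of equal-length literals.
#' @param id sequence id recorded in the result (default `""`).
#' @return data.frame with columns `seq_id`, `pattern`, `start`, `phase`.
#' @export
scan_motifs <- function(seq, patterns, id = "") {
  lens <- unique(nchar(patterns))
  out <- lapply(lens, function(k) {
    n <- nchar(seq)
    if (n < k) return(NULL)
    kmers <- substring(seq, 1:(n - k + 1), k:n)
    hit <- match(kmers, patterns)
    pos <- which(!is.na(hit))
    if (!length(pos)) return(NULL)
    data.frame(seq_id = id, pattern = patterns[hit[pos]],
               start = pos - 1L, phase = (pos - 1L) %% 3L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seq_id = character(), pattern = character(),
                      start = integer(), phase = integer(),
                      stringsAsFactors = FALSE)
  out[order(out$start, out$pattern), , drop = FALSE]
}

#' Phase-resolved motif frequency table for a genome
#'
#' Sums all (overlapping) occurrences of each pattern over all
#' sequences, split by phase. The table is zero-filled: it always has
#' `length(patterns) * 3` rows (192 cells for the 64 heptamers), is
#' independent of gene order, and is additive over genome chunks.
#'
#' @param genome named character vector of DNA sequences.
#' @param patterns equal-length motif literals (all 64 heptamers by
#'   default).
#' @return data.frame with columns `pattern`, `phase`, `count`;
#'   attributes `n_sequences` and `total_nt`.
#' @export
count_motif_frequencies <- function(genome, patterns = enumerate_heptamers()) {
  if (!length(genome)) stop("empty genome")
  patterns <- sort(patterns)
  m <- .count_patterns_cpp(unname(genome), patterns)
  out <- data.frame(pattern = rep(patterns, times = 3),
                    phase = rep(0:2, each = length(patterns)),
                    count = as.integer(m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pattern, out$phase), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sequences") <- length(genome)
  attr(out, "total_nt") <- sum(nchar(genome))
  out
}

#' Non-shifty control literal for a slippery motif
#'
#' Builds the mutant used as the no-motif background in reporter
#' assays. The substitutions keep the A-site tRNA (tetramers) or both
#' the P- and A-site tRNAs (heptamers) unchanged: for a tetramer
#' `Z_ZZN` only the first base is replaced (by `C` when Z is a purine,
#' giving `C_RRN`, else by `G`, giving `G_YYN`); for a heptamer
#' `X_XXZ_ZZN` the first base is replaced the same way (driven by X)
#' and the fourth base is replaced by the transition partner of Z
#' (A<->G, C<->T), a third-position change read by the same tRNA. This
#' resolves each motif to the unique member of the eight control
#' templates `{G_YY,C_RR} x {C_UUN, U_CCN, G_AAN, A_GGN}`.
#'
#' @param pattern character vector of motif literals (4 or 7 nt).
#' @return character vector of control literals; each differs from its
#'   motif at exactly the mandated positions (1st, or 1st and 4th).
#' @export
derive_nonshifty_control <- function(pattern) {
  vapply(pattern, function(p) {
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    if (p %in% enumerate_tetramers()) {
      z <- substr(p, 1, 1)
      paste0(if (is_purine(z)) "C" else "G", substr(p, 2, 4))
    } else if (p %in% enumerate_heptamers()) {
      x <- substr(p, 1, 1)
      z <- substr(p, 4, 4)
      paste0(if (is_purine(x)) "C" else "G", substr(p, 2, 3),
             transition[[z]], substr(p, 5, 7))
    } else {
      stop("'", p, "' is not a slippery tetramer or heptamer")
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Find open reading frames on the forward strand
#'
#' In each of the three frames, an ORF runs from the first start codon
#' (ATG/GTG/TTG) after the previous stop to the next in-frame stop
#' (inclusive), i.e. the longest ORF per stop. ORFs shorter than
#' `min_codons` (start and stop included) are dropped; ORFs without an
#' in-frame stop before the sequence end are not reported.
#'
#' @param seq single DNA string.
#' @param min_codons minimum ORF length in codons.
#' @return data.frame with 0-based half-open `start`, `end`, and
#'   `frame = start %% 3`.
#' @export
find_orfs <- function(seq, min_codons = 50,
                      start_codons = c("ATG", "GTG", "TTG")) {
  n <- nchar(seq)
  rows <- list()
  for (f in 0:2) {
    if (f > n - 3L) next
    starts0 <- seq.int(f, n - 3L, by = 3L)
    codons <- substring(seq, starts0 + 1, starts0 + 3)
    prev_stop <- 0L  # index into codons, 0 = before first
    i <- 1L
    while (i <= length(codons)) {
      if (codons[i] %in% STOP_CODONS) {
        seg <- if (prev_stop + 1L <= i - 1L)
          (prev_stop + 1L):(i - 1L) else integer()
        cand <- seg[codons[seg] %in% start_codons]
        if (length(cand)) {
          s <- cand[1]
          if (i - s + 1L >= min_codons)
            rows[[length(rows) + 1L]] <-
              data.frame(start = starts0[s], end = starts0[i] + 3L,
                         frame = starts0[s] %% 3L)
        }
        prev_stop <- i
      }
      i <- i + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), frame = integer())
  out[order(out$start, out$end), , drop = FALSE]
}

#' Census of slippery motifs in overlapping -1-frame ORF pairs
#'
#' Emulates the screen applied to insertion-sequence (IS) elements:
#' find ORF pairs where the downstream ORF lies in the -1 frame
#' relative to the upstream one (`start_B = start_A - 1 (mod 3)`) and
#' the two overlap, then report slippery motifs inside the overlap
#' region that sit in the shifty phase of the upstream ORF (motif start
#' at 2 mod 3 relative to the ORF start). Tetramer hits contained
#' within a reported heptamer hit of the same pair are suppressed, so a
#' planted heptamer yields one heptamer record and no tetramer record.
#'
#' @inheritParams find_orfs
#' @return data.frame with one row per (ORF pair, motif occurrence):
#'   `orf1_start`, `orf1_end`, `orf2_start`, `orf2_end`, `kind`
#'   (`"heptamer"`/`"tetramer"`), `pattern`, `start` (0-based in the
#'   element).
#' @export
scan_is_element <- function(seq, min_orf_codons = 50,
                            start_codons = c("ATG", "GTG", "TTG")) {
  empty <- data.frame(orf1_start = integer(), orf1_end = integer(),
                      orf2_start = integer(), orf2_end = integer(),
                      kind = character(), pattern = character(),
                      start = integer(), stringsAsFactors = FALSE)
  orfs <- find_orfs(seq, min_codons = min_orf_codons,
                    start_codons = start_codons)
  if (nrow(orfs) < 2) return(empty)
  hepts <- enumerate_heptamers()
  tets <- enumerate_tetramers()
  rows <- list()
  for (a in seq_len(nrow(orfs))) for (b in seq_len(nrow(orfs))) {
    if (a == b) next
    A <- orfs[a, ]; B <- orfs[b, ]
    if (B$start <= A$start) next
    if ((B$start %% 3L) != ((A$start - 1L) %% 3L + 3L) %% 3L) next
    ov_start <- max(A$start, B$start)
    ov_end <- min(A$end, B$end)
    if (ov_end <= ov_start) next
    region <- substr(seq, ov_start + 1L, ov_end)
    hits <- scan_motifs(region, c(hepts, tets))
    if (!nrow(hits)) next
    hits$start <- hits$start + ov_start
    hits$kind <- ifelse(nchar(hits$pattern) == 7L, "heptamer", "tetramer")
    # shifty phase relative to the upstream (frame-0) ORF
    hits <- hits[(hits$start - A$start) %% 3L == 2L, , drop = FALSE]
    # motif must lie entirely inside the overlap
    hits <- hits[hits$start + nchar(hits$pattern) <= ov_end, , drop = FALSE]
    if (!nrow(hits)) next
    hep <- hits[hits$kind == "heptamer", , drop = FALSE]
    tet <- hits[hits$kind == "tetramer", , drop = FALSE]
    if (nrow(tet) && nrow(hep)) {
      contained <- vapply(seq_len(nrow(tet)), function(i) {
        any(hep$start <= tet$start[i] & tet$start[i] + 4L <= hep$start + 7L)
      }, logical(1))
      tet <- tet[!contained, , drop = FALSE]
    }
    keep <- rbind(hep, tet)
    if (!nrow(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      orf1_start = A$start, orf1_end = A$end,
      orf2_start = B$start, orf2_end = B$end,
      kind = keep$kind, pattern = keep$pattern, start = keep$start,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
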