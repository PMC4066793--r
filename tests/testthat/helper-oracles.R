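# Independent brute-force oracles and fixture builders. These
# deliberately avoid the implementation's code paths (vectorized
# matching, C++ counting, the packaged ORF caller) so that agreement
# is informative.

# canonicalize a data.frame for implementation-vs-oracle comparison:
# strip row names, coerce every numeric column to double
norm_df <- function(d) {
  rownames(d) <- NULL
  d[] <- lapply(d, function(col) if (is.numeric(col)) as.numeric(col) else col)
  d
}

# naive sliding-window motif scan: position-by-position substring test
oracle_scan <- function(seq, patterns) {
  rows <- list()
  for (k in unique(nchar(patterns))) {
    pk <- patterns[nchar(patterns) == k]
    if (nchar(seq) < k) next
    for (i in seq_len(nchar(seq) - k + 1)) {
      sub <- substr(seq, i, i + k - 1)
      for (p in pk) {
        if (sub == p)
          rows[[length(rows) + 1]] <- data.frame(
            pattern = p, start = i - 1L, phase = (i - 1L) %% 3L,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(pattern = character(), start = integer(),
                      phase = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$pattern), , drop = FALSE]
}

oracle_dinuc_counts <- function(seq) {
  n <- nchar(seq)
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(substring(seq, 1:(n - 1), 2:n), levels = lv))
}

oracle_codon_multiset <- function(seq) {
  sort(substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3)))
}

# independent ORF enumeration: stop positions per frame via regular
# scan of codon vectors, starts chosen per segment
oracle_orfs <- function(seq, min_codons, starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    pos <- seq.int(f + 1, n - 2, by = 3)
    codons <- substring(seq, pos, pos + 2)
    stop_idx <- which(codons %in% stops)
    bound <- 0
    for (si in stop_idx) {
      segment <- setdiff(seq_len(si - 1), seq_len(bound))
      starts_in <- segment[codons[segment] %in% starts]
      if (length(starts_in)) {
        s <- min(starts_in)
        if (si - s + 1 >= min_codons)
          out[[length(out) + 1]] <- c(pos[s] - 1L, pos[si] + 2L)
      }
      bound <- si
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  out <- data.frame(start = m[, 1], end = m[, 2])
  out[order(out$start, out$end), , drop = FALSE]
}

oracle_is_census <- function(seq, min_codons) {
  orfs <- oracle_orfs(seq, min_codons)
  hepts <- enumerate_heptamers()
  tets <- enumerate_tetramers()
  rows <- list()
  if (nrow(orfs) >= 2) {
    for (a in seq_len(nrow(orfs))) for (b in seq_len(nrow(orfs))) {
      A <- orfs[a, ]; B <- orfs[b, ]
      if (B$start <= A$start) next
      if ((B$start %% 3) != ((A$start - 1) %% 3)) next
      ov1 <- max(A$start, B$start); ov2 <- min(A$end, B$end)
      if (ov2 <= ov1) next
      hep <- tet <- list()
      for (s in seq(ov1, ov2 - 1)) {
        if ((s - A$start) %% 3 != 2) next
        if (s + 7 <= ov2 && substr(seq, s + 1, s + 7) %in% hepts)
          hep[[length(hep) + 1]] <- c(s, match(substr(seq, s + 1, s + 7), hepts))
        if (s + 4 <= ov2 && substr(seq, s + 1, s + 4) %in% tets)
          tet[[length(tet) + 1]] <- c(s, match(substr(seq, s + 1, s + 4), tets))
      }
      hs <- vapply(hep, `[`, numeric(1), 1)
      for (h in hep)
        rows[[length(rows) + 1]] <- data.frame(
          orf1_start = A$start, orf2_start = B$start, kind = "heptamer",
          pattern = hepts[h[2]], start = h[1], stringsAsFactors = FALSE)
      for (t in tet) {
        if (any(hs <= t[1] & t[1] + 4 <= hs + 7)) next
        rows[[length(rows) + 1]] <- data.frame(
          orf1_start = A$start, orf2_start = B$start, kind = "tetramer",
          pattern = tets[t[2]], start = t[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(orf1_start = integer(), orf2_start = integer(),
                      kind = character(), pattern = character(),
                      start = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$orf1_start, out$orf2_start, out$start, out$kind), ,
      drop = FALSE]
}

# naive SD scan: explicit per-position degenerate comparisons over the
# full upstream region, spacing recomputed from first principles
oracle_scan_sd <- function(cds, motif_start) {
  base_match <- function(b, code) {
    switch(code,
           "N" = TRUE, "K" = b %in% c("T", "G"), b == code)
  }
  pats <- list(GAGG = "GAGG", GGAG = "GGAG", AGGA = "AGGA",
               GGNGG = "GGNGG", AGGKG = "AGGKG")
  seg_start <- max(0, motif_start - 30)
  hits <- list()
  for (nm in names(pats)) {
    tpl <- strsplit(pats[[nm]], "")[[1]]
    w <- length(tpl)
    for (s in seg_start:(motif_start - w)) {
      if (s < 0) next
      sub <- strsplit(substr(cds, s + 1, s + w), "")[[1]]
      if (length(sub) < w) next
      if (all(mapply(base_match, sub, tpl))) {
        spacing <- (motif_start + 1) - (s + w)
        if (spacing >= 6 && spacing <= 17)
          hits[[length(hits) + 1]] <- data.frame(
            sd_pattern = nm, start = s, spacing = spacing,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(sd_pattern = character(), start = integer(),
                      spacing = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$start, out$sd_pattern), , drop = FALSE]
}

# brute-force stacked-stem check: extract pairs by repeatedly removing
# innermost hairpin pairs, then walk outward-in from the first pair
oracle_closing_stem <- function(seq, structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  repeat {
    open <- -1; done <- TRUE
    for (i in seq_along(ch)) {
      if (ch[i] == "(") open <- i
      if (ch[i] == ")") {
        stopifnot(open > 0)
        pt[i] <- open; pt[open] <- i
        ch[i] <- "."; ch[open] <- "."
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  b <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  f <- which(pt != 0)[1]
  if (is.na(f)) return(list(first_pair_gc = FALSE, stacked_pairs_ok = FALSE))
  l <- pt[f]
  gc <- paste0(b[f], b[l]) %in% c("GC", "CG")
  ok <- TRUE
  for (k in 1:3) {
    i <- f + k; j <- l - k
    good <- i < j && pt[i] == j &&
      paste0(b[i], b[j]) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
    if (!good) { ok <- FALSE; break }
  }
  list(first_pair_gc = gc, stacked_pairs_ok = ok)
}

# ---------------------------------------------------------------------
# fixture builders

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(ecoli_codon_usage()),
                   c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# designed mobile-element fixture: ORF1 in frame 0, ORF2 starting at a
# -1-frame position inside it, one slippery heptamer in the overlap
make_planted_is_element <- function(motif = "AAAAAAG") {
  el <- paste0("ATG", strrep("CAC", 31), "TAA")   # ORF1: [0, 99)
  substr(el, 15, 17) <- "ATG"                     # ORF2 start at 14 (2 mod 3)
  substr(el, 51, 57) <- motif                     # motif at 50 (2 mod 3)
  paste0(el, strrep("CAC", 10), "CCTAA")          # ORF2 stop past ORF1 end
}

# random element with few stop codons, so overlapping ORFs are common
random_orf_rich_element <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(0.32, 0.28, 0.28, 0.12)), collapse = "")
}

# dot-bracket helices: stem of `bp` pairs around a loop, with optional
# leading/trailing unpaired tails
make_hairpin_structure <- function(bp, loop, lead = 0, trail = 0) {
  paste0(strrep(".", lead), strrep("(", bp), strrep(".", loop),
         strrep(")", bp), strrep(".", trail))
}

# complementary stem sequence realizing such a helix
make_hairpin_sequence <- function(stem, loop = "GAAA", lead = 0, trail = 0,
                                  filler = "A") {
  paste0(strrep(filler, lead), stem, loop, revcomp(stem),
         strrep(filler, trail))
}
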