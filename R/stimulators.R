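#' Folding-engine contract
#'
#' A folding engine predicts a minimum-free-energy secondary structure
#' for an RNA (or DNA, transcribed internally) sequence and returns a
#' dot-bracket string of the same length plus the folding free energy
#' at 37 degrees C in kcal/mol (negative for stable folds).
#' [vienna_engine()] wraps the `RNAfold` program; [stub_engine()] is a
#' deterministic table-driven engine for unit tests, returning a
#' precomputed `(structure, energy)` per sequence and an unfolded
#' structure at 0 kcal/mol for sequences absent from its table.
#'
#' @param fold_fun function(seq) -> list(structure, energy).
#' @param batch_fun optional vectorized version, function(seqs) ->
#'   list of such lists.
#' @param name engine label.
#' @return an object of class `"folding_engine"`.
#' @export
folding_engine <- function(fold_fun, batch_fun = NULL, name = "custom") {
  structure(list(fold_fun = fold_fun, batch_fun = batch_fun, name = name),
            class = "folding_engine")
}

#' @rdname folding_engine
#' @export
vienna_engine <- function() {
  if (!nzchar(Sys.which("RNAfold")))
    stop("RNAfold was not found on the PATH")
  batch <- function(seqs) {
    rna <- chartr("Tt", "Uu", toupper(seqs))
    out <- system2("RNAfold", c("--noPS"), input = paste(rna, collapse = "\n"),
                   stdout = TRUE, stderr = FALSE)
    out <- out[nzchar(out)]
    if (length(out) != 2L * length(seqs))
      stop("unexpected RNAfold output (", length(out), " lines for ",
           length(seqs), " sequences)")
    lapply(seq_along(seqs), function(i) {
      line <- out[2L * i]
      m <- regmatches(line, regexec("^(\\S+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", line))[[1]]
      if (length(m) != 3)
        stop("could not parse RNAfold output line: ", line)
      list(structure = m[2], energy = as.numeric(m[3]))
    })
  }
  folding_engine(function(seq) batch(seq)[[1]], batch, name = "vienna")
}

#' @rdname folding_engine
#' @param table data.frame with columns `seq`, `structure`, `energy`;
#'   lookups are exact on the (T->U normalized) sequence.
#' @export
stub_engine <- function(table) {
  key <- chartr("Tt", "Uu", toupper(table$seq))
  one <- function(seq) {
    k <- chartr("Tt", "Uu", toupper(seq))
    i <- match(k, key)
    if (is.na(i))
      list(structure = strrep(".", nchar(seq)), energy = 0)
    else
      list(structure = table$structure[i], energy = table$energy[i])
  }
  folding_engine(one, function(seqs) lapply(seqs, one), name = "stub")
}

#' @rdname folding_engine
#' @param engine a `"folding_engine"`.
#' @param seq,seqs sequence(s) to fold.
#' @export
fold <- function(engine, seq) {
  stopifnot(inherits(engine, "folding_engine"))
  res <- engine$fold_fun(seq)
  if (nchar(res$structure) != nchar(seq))
    stop("engine returned a structure of the wrong length")
  res
}

#' @rdname folding_engine
#' @export
fold_batch <- function(engine, seqs) {
  stopifnot(inherits(engine, "folding_engine"))
  if (!length(seqs)) return(list())
  if (!is.null(engine$batch_fun)) engine$batch_fun(seqs)
  else lapply(seqs, engine$fold_fun)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string (matched `(`/`)`, no
#'   pseudoknots).
#' @return integer vector: `pt[i]` is the 1-based partner of base `i`,
#'   or 0 when unpaired. Applying the result twice is the identity on
#'   paired positions.
#' @export
parse_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets in structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (chars[i] != ".") {
      stop("unexpected character '", chars[i], "' in structure")
    }
  }
  if (length(stack)) stop("unbalanced brackets in structure")
  pt
}

# Watson-Crick or G.U wobble pair?
is_wc_or_gu <- function(b1, b2) {
  p <- paste0(chartr("U", "T", b1), chartr("U", "T", b2))
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

#' Closing-stem check for a hairpin candidate
#'
#' The outermost pair of the structure element must be G-C or C-G and
#' must be followed (inward) by at least three consecutive paired
#' positions, each a Watson-Crick or G.U pair, with no intervening
#' bulge on either strand.
#'
#' @param seq sequence of the element (same coordinates as
#'   `structure`).
#' @param structure dot-bracket of the element; position 1 must pair
#'   with the last position of the element.
#' @return list with `first_pair_gc` and `stacked_pairs_ok`.
#' @export
check_closing_stem <- function(seq, structure) {
  pt <- parse_pairs(structure)
  b <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  f <- which(pt != 0)[1]
  if (is.na(f)) return(list(first_pair_gc = FALSE, stacked_pairs_ok = FALSE))
  l <- pt[f]
  gc <- paste0(b[f], b[l]) %in% c("GC", "CG")
  stacked <- TRUE
  for (k in 1:3) {
    i <- f + k; j <- l - k
    if (i >= j || pt[i] != j || !is_wc_or_gu(b[i], b[j])) {
      stacked <- FALSE
      break
    }
  }
  list(first_pair_gc = gc, stacked_pairs_ok = stacked)
}

#' Build a hairpin candidate from a folded downstream segment
#'
#' Converts one fold of (a 3' truncation of) the downstream segment
#' into a candidate record. The candidate is the outermost structure
#' element starting earliest: its span runs from the first paired base
#' to that base's partner. Distance is counted from the last motif
#' base: a structure starting at segment offset 0 is 4 nt after the
#' motif, because the segment itself starts at the fourth base after
#' the motif.
#'
#' @param segment the downstream segment (or truncation) that was
#'   folded.
#' @param structure its dot-bracket MFE structure.
#' @param energy its folding free energy (kcal/mol, negative when
#'   stable); `dG_unfold = -energy`.
#' @return one-row data.frame (`distance`, `length`, `structure`,
#'   `dG_unfold`, `dG_hp_per_nt`, `first_pair_gc`, `stacked_pairs_ok`),
#'   or `NULL` when the fold has no pairs.
#' @export
hairpin_candidate <- function(segment, structure, energy) {
  pt <- parse_pairs(structure)
  paired <- which(pt != 0)
  if (!length(paired)) return(NULL)
  f <- paired[1]
  l <- pt[f]
  len <- l - f + 1L
  element_seq <- substr(segment, f, l)
  element_struct <- substr(structure, f, l)
  stem <- check_closing_stem(element_seq, element_struct)
  dg_unfold <- -energy
  data.frame(distance = 4L + (f - 1L), length = len,
             structure = element_struct,
             dG_unfold = dg_unfold, dG_hp_per_nt = dg_unfold / len,
             first_pair_gc = stem$first_pair_gc,
             stacked_pairs_ok = stem$stacked_pairs_ok,
             stringsAsFactors = FALSE)
}

#' Empirical retention rules for hairpin stimulators
#'
#' A candidate downstream structure is retained when (i) its length
#' (first to last paired base, loops and bulges included) is 17-140
#' nt, (ii) it starts 4-10 nt after the last base of the motif,
#' (iii) its outermost pair is G-C or C-G followed by at least three
#' consecutive Watson-Crick or G.U pairs, and (iv) its unfolding
#' energy is at least 7.6 kcal/mol. All bounds are inclusive.
#'
#' @param candidate one-row data.frame from [hairpin_candidate()].
#' @return logical.
#' @export
passes_hairpin_rules <- function(candidate) {
  if (is.null(candidate) || !nrow(candidate)) return(logical(0))
  candidate$length >= 17 & candidate$length <= 140 &
    candidate$distance >= 4 & candidate$distance <= 10 &
    candidate$first_pair_gc & candidate$stacked_pairs_ok &
    candidate$dG_unfold >= 7.6
}

# 0-based start of the downstream segment: the fourth base after the
# last base of the motif
segment_start0 <- function(motif_start, motif_len)
  as.integer(motif_start) + as.integer(motif_len) + 3L

extract_segment <- function(cds, motif_start, motif_len, max_segment = 197L) {
  s0 <- segment_start0(motif_start, motif_len)
  if (s0 >= nchar(cds)) return("")
  substr(cds, s0 + 1L, min(nchar(cds), s0 + max_segment))
}

#' Enumerate retained hairpin stimulator candidates downstream of a motif
#'
#' Extracts the downstream segment (up to 197 nt starting at the
#' fourth base after the motif, truncated at the sequence end), folds
#' every 3'-truncation prefix from the full length down to 17 nt,
#' converts each fold to a candidate ([hairpin_candidate()]), retains
#' those satisfying [passes_hairpin_rules()], and deduplicates
#' identical (structure, length, distance) triples.
#'
#' @param cds DNA sequence containing the motif.
#' @param motif_start 0-based motif start in `cds`.
#' @param motif_len motif length (7 for heptamers).
#' @param engine a [folding_engine()].
#' @param max_segment segment length cap (197 nt).
#' @param min_prefix shortest prefix folded (17 nt).
#' @return data.frame of retained candidates (possibly 0 rows), with a
#'   `prefix_len` column recording the truncation that produced each.
#' @export
enumerate_hairpins <- function(cds, motif_start, motif_len = 7L, engine,
                               max_segment = 197L, min_prefix = 17L) {
  segment <- extract_segment(cds, motif_start, motif_len, max_segment)
  empty <- data.frame(distance = integer(), length = integer(),
                      structure = character(), dG_unfold = numeric(),
                      dG_hp_per_nt = numeric(), first_pair_gc = logical(),
                      stacked_pairs_ok = logical(), prefix_len = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(segment) < min_prefix) return(empty)
  lens <- seq.int(nchar(segment), min_prefix)
  prefixes <- substring(segment, 1L, lens)
  folds <- fold_batch(engine, prefixes)
  rows <- list()
  for (i in seq_along(lens)) {
    cand <- hairpin_candidate(prefixes[i], folds[[i]]$structure,
                              folds[[i]]$energy)
    if (is.null(cand)) next
    if (!passes_hairpin_rules(cand)) next
    cand$prefix_len <- lens[i]
    rows[[length(rows) + 1L]] <- cand
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("structure", "length", "distance")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan upstream of a motif for Shine-Dalgarno-like stimulators
#'
#' Scans the 30-nt segment ending at (and excluding) the first base of
#' the motif for the experimentally validated SD-like patterns GAGG,
#' GGAG, AGGA, GGNGG and AGGKG (K = T or G), truncating at the
#' sequence start. A match is retained when its spacing lies in 6-17
#' nt; the spacing convention is the number of nucleotides strictly
#' between the last base of the SD match and the second base of the
#' motif, plus one (so an SD followed by 9 spacer nt before the motif
#' has spacing 10).
#'
#' @param cds DNA sequence containing the motif.
#' @param motif_start 0-based motif start.
#' @param min_spacing,max_spacing inclusive spacing bounds (nt).
#' @return data.frame with columns `sd_pattern`, `match`, `start`
#'   (0-based in `cds`), `spacing`.
#' @export
scan_sd <- function(cds, motif_start, min_spacing = 6L, max_spacing = 17L) {
  motif_start <- as.integer(motif_start)
  sd_patterns <- c(GAGG = "GAGG", GGAG = "GGAG", AGGA = "AGGA",
                   GGNGG = "GG[ACGT]GG", AGGKG = "AGG[TG]G")
  seg_start <- max(0L, motif_start - 30L)
  segment <- substr(cds, seg_start + 1L, motif_start)
  empty <- data.frame(sd_pattern = character(), match = character(),
                      start = integer(), spacing = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(segment)) return(empty)
  rows <- list()
  for (nm in names(sd_patterns)) {
    w <- if (nm %in% c("GGNGG", "AGGKG")) 5L else 4L
    m <- gregexpr(paste0("(?=", sd_patterns[[nm]], ")"), segment,
                  perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (p in as.integer(m)) {  # 1-based match start within segment
      abs_start <- seg_start + p - 1L
      sd_end <- abs_start + w              # 0-based exclusive
      spacing <- (motif_start + 1L) - sd_end
      if (spacing >= min_spacing && spacing <= max_spacing)
        rows[[length(rows) + 1L]] <- data.frame(
          sd_pattern = nm,
          match = substr(cds, abs_start + 1L, abs_start + w),
          start = abs_start, spacing = spacing, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$sd_pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a cluster have a conserved SD stimulator?
#'
#' @param sd_hits_per_member list of [scan_sd()] results, one per
#'   member; `n_all` defaults to its length.
#' @param n_all cluster size used as the denominator.
#' @return `TRUE` when at least 50% of the members have an SD hit.
#' @export
cluster_sd_conserved <- function(sd_hits_per_member,
                                 n_all = length(sd_hits_per_member)) {
  with_sd <- sum(vapply(sd_hits_per_member, nrow, integer(1)) > 0)
  with_sd / n_all >= 0.5
}

#' Group hairpin candidates into structure types over a cluster
#'
#' Candidates are grouped by exact (length, distance); the frequency
#' of a type is the fraction of cluster members exhibiting it (a
#' member counts once per type), and only types present in at least
#' 50% of the members are retained. The best type maximizes the score
#' `mean(dG_hp_per_nt) * frequency`, with ties broken by larger
#' `dG_hp_per_nt`, then smaller distance.
#'
#' @param candidates_per_member list of [enumerate_hairpins()] results.
#' @param n_all cluster size used as the denominator.
#' @return data.frame of retained types (`length`, `distance`,
#'   `frequency`, `dG_hp_per_nt`, `score`), best first; attribute
#'   `"best"` holds the top row (or `NULL`).
#' @export
group_structure_types <- function(candidates_per_member,
                                  n_all = length(candidates_per_member)) {
  per_type <- list()
  for (cand in candidates_per_member) {
    if (is.null(cand) || !nrow(cand)) next
    keys <- paste(cand$length, cand$distance)
    for (key in unique(keys)) {
      rows <- cand[keys == key, , drop = FALSE]
      per_type[[key]] <- c(per_type[[key]], max(rows$dG_hp_per_nt))
    }
  }
  empty <- data.frame(length = integer(), distance = integer(),
                      frequency = numeric(), dG_hp_per_nt = numeric(),
                      score = numeric())
  if (!length(per_type)) {
    attr(empty, "best") <- NULL
    return(empty)
  }
  out <- do.call(rbind, lapply(names(per_type), function(key) {
    ld <- as.integer(strsplit(key, " ")[[1]])
    data.frame(length = ld[1], distance = ld[2],
               frequency = length(per_type[[key]]) / n_all,
               dG_hp_per_nt = mean(per_type[[key]]))
  }))
  out <- out[out$frequency >= 0.5, , drop = FALSE]
  if (!nrow(out)) {
    attr(out, "best") <- NULL
    return(out)
  }
  out$score <- out$dG_hp_per_nt * out$frequency
  out <- out[order(-out$score, -out$dG_hp_per_nt, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best") <- out[1, , drop = FALSE]
  out
}

#' Sliding-window folding-energy enrichment of a hairpin
#'
#' Measures whether the region downstream of a motif is more
#' structured than its neighbourhood: over the 197-nt downstream
#' segment, every window of the conserved hairpin's size (step 1 nt)
#' is folded; `dG_av_per_nt` is the mean of `-energy / window_size`
#' over windows, and `ddG_per_nt = dG_hp_per_nt - dG_av_per_nt`. A
#' value of at least 0.09 kcal/mol/nt marks IS-like structural
#' enrichment.
#'
#' @inheritParams enumerate_hairpins
#' @param hairpin_length window size, nt (17-197).
#' @param dG_hp_per_nt per-nucleotide unfolding energy of the
#'   conserved hairpin.
#' @param threshold enrichment threshold (kcal/mol/nt).
#' @return list with `dG_hp_per_nt`, `dG_av_per_nt`, `ddG_per_nt`,
#'   `sd_window`, `n_windows`, `passes_is_threshold`.
#' @export
compute_ddg <- function(cds, motif_start, motif_len = 7L, hairpin_length,
                        dG_hp_per_nt, engine, max_segment = 197L,
                        threshold = 0.09) {
  if (hairpin_length > max_segment)
    stop("hairpin length exceeds the segment size")
  segment <- extract_segment(cds, motif_start, motif_len, max_segment)
  if (nchar(segment) < hairpin_length)
    stop("segment (", nchar(segment), " nt) shorter than the window (",
         hairpin_length, " nt)")
  starts <- seq_len(nchar(segment) - hairpin_length + 1L)
  windows <- substring(segment, starts, starts + hairpin_length - 1L)
  folds <- fold_batch(engine, windows)
  vals <- vapply(folds, function(f) -f$energy / hairpin_length, numeric(1))
  av <- mean(vals)
  ddg <- dG_hp_per_nt - av
  list(dG_hp_per_nt = dG_hp_per_nt, dG_av_per_nt = av, ddG_per_nt = ddg,
       sd_window = if (length(vals) > 1) sd(vals) else 0,
       n_windows = length(vals),
       passes_is_threshold = ddg >= threshold)
}
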