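#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62 for proteins, +1/-2
#' match/mismatch for nucleotides, affine gaps); identity is the number
#' of matching columns divided by the total number of alignment
#' columns, terminal gaps included.
#'
#' @param a,b sequences (DNA or protein, per `level`).
#' @param level `"nucleotide"` or `"protein"`.
#' @return identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  aln <- align_pair(a, b, level)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

align_pair <- function(a, b, level) {
  if (level == "protein") {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, type = "global")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE)
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, type = "global")
  }
}

#' Greedy single-linkage-to-representative clustering
#'
#' Incremental greedy clustering in input order: each sequence joins
#' the first existing cluster whose representative (its founding
#' sequence) has global-alignment identity at or above the threshold,
#' otherwise it founds a new cluster. The result is a partition and is
#' deterministic for a fixed input order. Used at 0.95 on nucleotide
#' sequences for redundancy removal and at 0.45 on proteins to build
#' gene families.
#'
#' @param seqs named character vector.
#' @param threshold identity threshold in `[0, 1]`.
#' @param level `"nucleotide"` or `"protein"`.
#' @return list with `assignment` (named integer cluster index per
#'   sequence), `members` (list of id vectors) and `representatives`
#'   (one id per cluster).
#' @export
greedy_cluster <- function(seqs, threshold = 0.95,
                           level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  if (!length(seqs)) stop("need at least one sequence")
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  reps <- character()
  assignment <- setNames(integer(length(seqs)), names(seqs))
  for (i in seq_along(seqs)) {
    placed <- 0L
    for (k in seq_along(reps)) {
      if (pairwise_identity(seqs[[i]], seqs[[reps[k]]], level) >= threshold) {
        placed <- k
        break
      }
    }
    if (placed == 0L) {
      reps <- c(reps, names(seqs)[i])
      placed <- length(reps)
    }
    assignment[i] <- placed
  }
  members <- split(names(assignment), assignment)
  names(members) <- NULL
  list(assignment = assignment, members = members, representatives = reps)
}

#' Star multiple alignment around the longest sequence
#'
#' Builds a simple multiple alignment by aligning every sequence to the
#' longest member (the star center) with global pairwise alignment and
#' merging the pairwise gap patterns; insertions relative to the center
#' are padded across all rows. Externally produced alignments, when
#' available, are preferable; this built-in keeps the pipeline
#' self-contained.
#'
#' @param seqs named character vector (>= 1 sequence).
#' @param level `"protein"` (default) or `"nucleotide"`.
#' @return named character vector of equal-length gapped rows, in the
#'   input order.
#' @export
star_align <- function(seqs, level = c("protein", "nucleotide")) {
  level <- match.arg(level)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (length(seqs) == 1) return(seqs)
  center_id <- names(seqs)[which.max(nchar(seqs))]
  center <- seqs[[center_id]]
  L <- nchar(center)
  others <- setdiff(names(seqs), center_id)

  # pairwise alignments member vs center, recorded as gapped strings
  pair <- lapply(others, function(id) {
    aln <- align_pair(seqs[[id]], center, level)
    list(mem = as.character(Biostrings::alignedPattern(aln)),
         cen = as.character(Biostrings::alignedSubject(aln)))
  })
  names(pair) <- others

  # ins[p + 1]: member characters inserted before center position p
  # (0-based; slot L + 1 collects trailing insertions)
  ins_of <- function(cen_gapped) {
    ins <- integer(L + 1)
    p <- 0L
    for (ch in strsplit(cen_gapped, "")[[1]]) {
      if (ch == "-") ins[p + 1L] <- ins[p + 1L] + 1L else p <- p + 1L
    }
    ins
  }
  all_ins <- lapply(pair, function(x) ins_of(x$cen))
  master <- Reduce(pmax, all_ins, integer(L + 1))

  pad <- function(k) strrep("-", k)
  center_row <- paste0(
    paste0(vapply(seq_len(L), function(p)
      paste0(pad(master[p]), substr(center, p, p)), character(1)),
      collapse = ""),
    pad(master[L + 1L]))

  expand_member <- function(px) {
    mem <- strsplit(px$mem, "")[[1]]
    cen <- strsplit(px$cen, "")[[1]]
    out <- character(0)
    p <- 0L
    buf <- character(0)  # member chars inserted before next center pos
    flush <- function(slot, aligned_char) {
      c(pad(master[slot] - length(buf)), buf, aligned_char)
    }
    for (i in seq_along(cen)) {
      if (cen[i] == "-") {
        buf <- c(buf, mem[i])
      } else {
        p <- p + 1L
        out <- c(out, flush(p, mem[i]))
        buf <- character(0)
      }
    }
    out <- c(out, pad(master[L + 1L] - length(buf)), buf)
    paste0(out, collapse = "")
  }

  rows <- setNames(vector("character", length(seqs)), names(seqs))
  rows[center_id] <- center_row
  for (id in others) rows[id] <- expand_member(pair[[id]])
  if (length(unique(nchar(rows))) != 1)
    stop("internal error: star alignment rows differ in length")
  rows[names(seqs)]
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column expands to three nucleotide columns; gap
#' characters expand to `---`, so codons are never split across a gap
#' block and degapping any row reproduces its source CDS.
#'
#' @param protein_aln named character vector of gapped protein rows.
#' @param cds named character vector of the corresponding CDSs; each
#'   degapped protein row must equal `translate_cds()` of its CDS.
#' @return named character vector of gapped nucleotide rows.
#' @export
back_translate_alignment <- function(protein_aln, cds) {
  missing <- setdiff(names(protein_aln), names(cds))
  if (length(missing))
    stop("no CDS for row(s): ", paste(missing, collapse = ", "))
  out <- vapply(names(protein_aln), function(id) {
    row <- strsplit(protein_aln[[id]], "")[[1]]
    prot <- translate_cds(cds[[id]])
    if (paste(row[row != "-"], collapse = "") != prot)
      stop("protein row '", id, "' does not match the translation of its CDS")
    codons <- substring(cds[[id]], seq(1, nchar(cds[[id]]), 3),
                        seq(3, nchar(cds[[id]]), 3))
    j <- 0L
    paste0(vapply(row, function(ch) {
      if (ch == "-") "---" else { j <<- j + 1L; codons[j] }
    }, character(1)), collapse = "")
  }, character(1))
  setNames(out, names(protein_aln))
}

#' N1/N2/N3 conservation tally for a gene cluster
#'
#' Classifies every member of a codon-aligned cluster by how well it
#' conserves the cluster's parent slippery heptamer, in priority
#' order: `N1` when the exact parent literal sits at the conserved
#' alignment column (mapped through the member's gaps), else `N2` when
#' any of the 64 heptamers sits there, else `N3` when any heptamer
#' occurs within a window (default 36 nt in the member's ungapped
#' coordinates, starting 15 nt upstream of the mapped site, truncated
#' at the sequence ends). Members with a gap at the conserved column
#' are eligible for the window category only. The categories are
#' mutually exclusive, so `N1 + N2 + N3 <= N_all` and the conservation
#' rule `N_sum / N_all > 0.9` is well defined. Eligibility additionally
#' requires at least `min_members` sequences.
#'
#' @param nuc_alignment named character vector of gapped CDS rows.
#' @param parent_pattern the cluster's heptamer literal.
#' @param conserved_column 0-based alignment column of the pattern
#'   start.
#' @param window_upstream,window_len window geometry in nt.
#' @param min_members minimum cluster size for eligibility.
#' @return list with `N_all`, `N1`, `N2`, `N3`, `N_sum`, `ratio`,
#'   `conserved` (strict `ratio > 0.9`), `eligible`, and the per-member
#'   `category` (`"N1"`, `"N2"`, `"N3"` or `"none"`).
#' @export
tally_conservation <- function(nuc_alignment, parent_pattern,
                               conserved_column, window_upstream = 15,
                               window_len = 36, min_members = 20) {
  stopifnot(parent_pattern %in% enumerate_heptamers())
  hepts <- enumerate_heptamers()
  category <- setNames(character(length(nuc_alignment)), names(nuc_alignment))
  for (id in names(nuc_alignment)) {
    row <- nuc_alignment[[id]]
    seqd <- gsub("-", "", row, fixed = TRUE)
    at_site <- NA_character_
    chars <- strsplit(row, "")[[1]]
    if (conserved_column < 0 || conserved_column >= length(chars))
      stop("conserved column out of range for row '", id, "'")
    gap_at_site <- chars[conserved_column + 1L] == "-"
    pos <- if (gap_at_site) ungapped_prefix_length(row, conserved_column)
           else map_to_position(row, conserved_column)
    if (!gap_at_site && pos + 7L <= nchar(seqd))
      at_site <- substr(seqd, pos + 1L, pos + 7L)
    if (!gap_at_site && !is.na(at_site) && at_site == parent_pattern) {
      category[id] <- "N1"
    } else if (!gap_at_site && !is.na(at_site) && at_site %in% hepts) {
      category[id] <- "N2"
    } else {
      ws <- max(0L, pos - as.integer(window_upstream))
      we <- min(nchar(seqd), ws + as.integer(window_len))
      window <- if (we > ws) substr(seqd, ws + 1L, we) else ""
      hit <- nzchar(window) && nrow(scan_motifs(window, hepts)) > 0
      category[id] <- if (hit) "N3" else "none"
    }
  }
  n_all <- length(category)
  n1 <- sum(category == "N1"); n2 <- sum(category == "N2")
  n3 <- sum(category == "N3")
  ratio <- (n1 + n2 + n3) / n_all
  list(N_all = n_all, N1 = n1, N2 = n2, N3 = n3, N_sum = n1 + n2 + n3,
       ratio = ratio, conserved = ratio > 0.9,
       eligible = n_all >= min_members, category = category)
}
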