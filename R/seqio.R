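#' Read a FASTA file into a named character vector
#'
#' Sequences are returned as a named character vector (names are record
#' ids, i.e. the first whitespace-delimited token of each header); the
#' remainder of each header is kept in the `"desc"` attribute. For the
#' DNA alphabet, `U` is normalized to `T` and lower case to upper case.
#' Records containing characters outside the alphabet are skipped with a
#' warning, or rejected when `strict = TRUE`.
#'
#' @param path path to a (multi-)FASTA file, wrapped or unwrapped.
#' @param alphabet `"DNA"` (A/C/G/T after U->T normalization) or
#'   `"protein"` (the 20 amino acids plus `*` and `-`).
#' @param strict abort on an invalid record instead of skipping it.
#' @return named character vector with a `"desc"` attribute.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "protein"), strict = FALSE) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(headers)))
    stop("malformed FASTA header in '", path, "'")
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (alphabet == "DNA") seqs <- chartr("U", "T", seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s) at index ",
         paste(which(empty), collapse = ", "), " in '", path, "'")
  }
  pat <- if (alphabet == "DNA") "^[ACGT-]+$" else "^[ACDEFGHIKLMNPQRSTVWY*-]+$"
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    msg <- paste0(sum(bad), " record(s) with characters outside the ",
                  alphabet, " alphabet: ",
                  paste(head(ids[bad], 5), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; skipped")
    ids <- ids[!bad]; desc <- desc[!bad]; seqs <- seqs[!bad]
  }
  out <- setNames(seqs, ids)
  attr(out, "desc") <- setNames(desc, ids)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector; an optional `"desc"` attribute
#'   (as produced by [read_fasta()]) is appended to each header.
#' @param path output path.
#' @param width line-wrap width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  desc <- attr(seqs, "desc")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    d <- if (!is.null(desc) && id %in% names(desc) && nzchar(desc[[id]]))
      paste0(" ", desc[[id]]) else ""
    cat(">", id, d, "\n", sep = "", file = con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      s <- paste(substring(s, starts, pmin(starts + width - 1, nchar(s))),
                 collapse = "\n")
    }
    cat(s, "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Validate a coding sequence
#'
#' A valid CDS is a non-empty A/C/G/T string whose length is divisible
#' by 3 (the terminal stop codon, when present, is part of the CDS).
#'
#' @param seq single DNA string.
#' @return `TRUE`/`FALSE` for [is_valid_cds()]; [validate_cds()] returns
#'   `seq` invisibly or signals an error describing the violation.
#' @export
is_valid_cds <- function(seq) {
  nzchar(seq) && nchar(seq) %% 3 == 0 && grepl("^[ACGT]+$", seq)
}

#' @rdname is_valid_cds
#' @export
validate_cds <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  if (nchar(seq) %% 3 != 0)
    stop("CDS length ", nchar(seq), " is not divisible by 3")
  if (!grepl("^[ACGT]+$", seq))
    stop("CDS contains characters outside {A,C,G,T} (ambiguity codes are rejected)")
  invisible(seq)
}

#' Filter a genome down to valid coding sequences
#'
#' @param genome named character vector of putative CDSs.
#' @param strict abort on the first invalid record instead of skipping.
#' @return the valid subset, with a warning listing skip counts.
#' @export
validate_genome <- function(genome, strict = FALSE) {
  ok <- vapply(genome, is_valid_cds, logical(1))
  if (any(!ok)) {
    if (strict)
      stop(sum(!ok), " invalid CDS record(s): ",
           paste(head(names(genome)[!ok], 5), collapse = ", "))
    warning(sum(!ok), " invalid CDS record(s) skipped")
  }
  genome[ok]
}

#' Translate coding sequences
#'
#' Translation uses the bacterial/archaeal code (NCBI table 11); stop
#' codons are rendered as `*`. Every codon of a validated CDS has a
#' defined translation, so the result always has `nchar(cds) / 3`
#' residues.
#'
#' @param cds character vector of valid CDSs.
#' @return character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  for (s in cds) validate_cds(s)
  out <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds),
    genetic.code = Biostrings::getGeneticCode("11")))
  setNames(out, names(cds))
}

#' Map between ungapped positions and alignment columns
#'
#' For one gapped alignment row, [map_to_column()] converts a 0-based
#' ungapped residue position to its 0-based alignment column, and
#' [map_to_position()] is its inverse (defined only on non-gap
#' columns). The two compose to the identity on all valid inputs.
#'
#' @param row single gapped string (gap character `-`).
#' @param pos 0-based ungapped position(s).
#' @param column 0-based alignment column(s).
#' @return integer vector of 0-based columns / positions.
#' @export
map_to_column <- function(row, pos) {
  nongap <- which(strsplit(row, "")[[1]] != "-")
  if (any(pos < 0 | pos >= length(nongap)))
    stop("ungapped position out of range [0, ", length(nongap), ")")
  nongap[pos + 1L] - 1L
}

#' @rdname map_to_column
#' @export
map_to_position <- function(row, column) {
  chars <- strsplit(row, "")[[1]]
  if (any(column < 0 | column >= length(chars)))
    stop("column out of range [0, ", length(chars), ")")
  if (any(chars[column + 1L] == "-"))
    stop("column is a gap in this row")
  cum <- cumsum(chars != "-")
  cum[column + 1L] - 1L
}

#' Read an aligned FASTA file
#'
#' @inheritParams read_fasta
#' @return named character vector of equal-length gapped rows.
#' @export
read_alignment <- function(path, alphabet = c("DNA", "protein")) {
  aln <- read_fasta(path, alphabet = match.arg(alphabet), strict = TRUE)
  if (length(unique(nchar(aln))) > 1)
    stop("alignment rows differ in length")
  aln
}

# number of non-gap characters in row up to (excluding) column `col0`;
# used to anchor window scans when a member has a gap at a mapped site
ungapped_prefix_length <- function(row, col0) {
  if (col0 <= 0) return(0L)
  sum(strsplit(substr(row, 1L, col0), "")[[1]] != "-")
}
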