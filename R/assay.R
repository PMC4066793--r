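#' Frameshift percentage from reporter activities
#'
#' Frameshifting frequency is expressed relative to an in-frame
#' construct serving as the 100% reference: each replicate activity is
#' divided by the mean reference activity and scaled to percent, and
#' the mean and standard deviation over replicates are reported. The
#' estimate is invariant to rescaling all activities and the reference
#' by a common factor.
#'
#' @param activities positive replicate activities (Miller-unit scale).
#' @param reference_activities positive replicate activities of the
#'   matching in-frame construct.
#' @return list with `percent` and `sd`.
#' @export
frameshift_percent <- function(activities, reference_activities) {
  if (!length(activities)) stop("need at least one replicate activity")
  ref <- mean(reference_activities)
  if (!is.finite(ref) || ref <= 0) stop("non-positive reference activity")
  if (any(activities <= 0)) stop("activities must be positive")
  ratios <- 100 * activities / ref
  list(percent = mean(ratios),
       sd = if (length(ratios) > 1) sd(ratios) else 0)
}

#' Motif/no-motif ratio classifier
#'
#' The ratio between a motif construct's frameshift percentage and its
#' non-shifty control's percentage classifies the motif: strictly
#' above 2 is frameshift-prone. The classifier is monotone in the
#' motif percentage and antitone in the control percentage.
#'
#' @param motif_percent,control_percent frameshift percentages.
#' @return list with `ratio` and `prone`.
#' @export
classify_motif <- function(motif_percent, control_percent) {
  if (control_percent <= 0) stop("control percentage must be positive")
  ratio <- motif_percent / control_percent
  list(ratio = ratio, prone = ratio > 2)
}

#' Mean and standard deviation of background frameshifting
#'
#' @param percents frameshift percentages of no-motif constructs.
#' @return list with `mean` and `sd`.
#' @export
summarize_background <- function(percents) {
  list(mean = mean(percents),
       sd = if (length(percents) > 1) sd(percents) else 0)
}

#' Per-construct frameshift percentages for one assay context
#'
#' Expects a long-format assay table with one row per replicate and
#' columns `context`, `motif` (literal, or `NA` for the reference),
#' `role` (`"motif"`, `"control"`, `"reference"`) and `activity`. All
#' constructs of a context share that context's in-frame reference.
#'
#' @param table assay data.frame.
#' @param context context label to analyse.
#' @return data.frame with one row per (motif, role): `motif`, `role`,
#'   `percent`, `sd`, `n_replicates`.
#' @export
estimate_percents <- function(table, context) {
  tab <- table[table$context == context, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for context '", context, "'")
  ref <- tab$activity[tab$role == "reference"]
  if (!length(ref)) stop("no in-frame reference rows for context '",
                         context, "'")
  keys <- unique(tab[tab$role != "reference", c("motif", "role")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    act <- tab$activity[tab$motif %in% keys$motif[i] &
                          tab$role == keys$role[i]]
    est <- frameshift_percent(act, ref)
    data.frame(motif = keys$motif[i], role = keys$role[i],
               percent = est$percent, sd = est$sd,
               n_replicates = length(act), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Count frameshift-prone motifs in an assay context
#'
#' Applies the ratio-above-2 classifier to every motif of a context.
#' The denominator is the motif's own non-shifty control when control
#' constructs exist; otherwise a context-wide scalar `background`
#' percentage must be supplied (used for contexts whose per-motif
#' controls were not assayed).
#'
#' @inheritParams estimate_percents
#' @param background optional scalar background percentage.
#' @return list with `n_motifs`, `n_prone`, `prone` and `below`
#'   (motif literals), and the per-motif `ratios`.
#' @export
count_prone <- function(table, context, background = NULL) {
  est <- estimate_percents(table, context)
  motifs <- est[est$role == "motif", , drop = FALSE]
  controls <- est[est$role == "control", , drop = FALSE]
  ratios <- vapply(seq_len(nrow(motifs)), function(i) {
    ctrl <- if (!is.null(background)) background
    else {
      j <- match(motifs$motif[i], controls$motif)
      if (is.na(j)) stop("no control construct for motif '",
                         motifs$motif[i], "' and no background given")
      controls$percent[j]
    }
    classify_motif(motifs$percent[i], ctrl)$ratio
  }, numeric(1))
  names(ratios) <- motifs$motif
  prone <- names(ratios)[ratios > 2]
  list(n_motifs = length(ratios), n_prone = length(prone),
       prone = sort(prone), below = sort(setdiff(names(ratios), prone)),
       ratios = ratios)
}
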