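# a deterministic stub engine over a fixture table is used wherever a
# real folding prediction is not the point

test_that("dot-bracket parsing is an involution and rejects bad input", {
  pt <- parse_pairs("((..))")
  expect_identical(pt, c(6L, 5L, 0L, 0L, 2L, 1L))
  paired <- which(pt != 0)
  expect_identical(pt[pt[paired]], paired)
  expect_error(parse_pairs("(()"), "unbalanced")
  expect_error(parse_pairs("())"), "unbalanced")
  expect_error(parse_pairs("(x)"), "unexpected")
})

test_that("closing-stem detector agrees with the brute-force stack walk", {
  set.seed(60)
  for (i in 1:80) {
    bp <- sample(2:10, 1)
    loop <- sample(3:6, 1)
    lead <- sample(0:4, 1)
    struct <- make_hairpin_structure(bp, loop, lead = lead,
                                     trail = sample(0:3, 1))
    stem <- paste(sample(c("A", "C", "G", "T"), bp, replace = TRUE),
                  collapse = "")
    seq <- make_hairpin_sequence(stem, strrep("A", loop), lead = lead,
                                 trail = nchar(struct) - lead - 2 * bp - loop)
    seq <- substr(seq, 1, nchar(struct))
    got <- check_closing_stem(seq, struct)
    want <- oracle_closing_stem(seq, struct)
    expect_identical(got, want)
  }
})

test_that("SD scanning applies the frozen spacing convention", {
  # GGAG, then 9 spacer nt, then the motif: spacing 10
  cds <- paste0(strrep("C", 20), "GGAG", strrep("C", 9), "AAAAAAG",
                strrep("C", 10))
  hits <- scan_sd(cds, motif_start = 33)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$sd_pattern, "GGAG")
  expect_identical(hits$spacing, 10L)

  expect_identical(nrow(scan_sd(strrep("C", 60), 40)), 0L)

  # degenerate patterns match through N and K positions
  cds2 <- paste0(strrep("C", 20), "GGTGG", strrep("C", 8), "AAAAAAG",
                 strrep("C", 10))
  h2 <- scan_sd(cds2, motif_start = 33)
  expect_true("GGNGG" %in% h2$sd_pattern)
})

test_that("SD scanning agrees with the positional oracle on random segments", {
  set.seed(61)
  n_hits <- 0
  for (i in 1:150) {
    cds <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                        prob = c(0.3, 0.15, 0.4, 0.15)), collapse = "")
    m <- sample(35:50, 1)
    got <- scan_sd(cds, m)[, c("sd_pattern", "start", "spacing")]
    want <- oracle_scan_sd(cds, m)
    expect_identical(norm_df(got), norm_df(want))
    n_hits <- n_hits + nrow(want)
  }
  expect_gt(n_hits, 20)
})

test_that("cluster SD conservation uses the inclusive 50% rule", {
  hit <- scan_sd(paste0(strrep("C", 20), "GGAG", strrep("C", 9), "AAAAAAG"),
                 33)
  none <- scan_sd(strrep("C", 40), 35)
  expect_true(cluster_sd_conserved(c(rep(list(hit), 5), rep(list(none), 5))))
  expect_false(cluster_sd_conserved(c(rep(list(hit), 4), rep(list(none), 6))))
  expect_false(cluster_sd_conserved(rep(list(none), 3)))
})

test_that("hairpin retention rules hold exactly at every threshold edge", {
  segment <- strrep("A", 197)
  mk <- function(length, distance, dG) {
    bp <- 5
    inner_dots <- length - 2 * bp
    struct <- paste0(strrep("(", bp), strrep(".", inner_dots),
                     strrep(")", bp))
    stem <- "GCGCG"
    seq <- paste0(stem, strrep("A", inner_dots), revcomp(stem))
    cand <- hairpin_candidate(
      paste0(strrep("A", distance - 4), seq),
      paste0(strrep(".", distance - 4), struct),
      -dG)
    cand
  }
  for (case in list(
    list(length = 16, distance = 5, dG = 10, pass = FALSE),
    list(length = 17, distance = 5, dG = 10, pass = TRUE),
    list(length = 140, distance = 5, dG = 10, pass = TRUE),
    list(length = 141, distance = 5, dG = 10, pass = FALSE),
    list(length = 30, distance = 4, dG = 10, pass = TRUE),
    list(length = 30, distance = 10, dG = 10, pass = TRUE),
    list(length = 30, distance = 11, dG = 10, pass = FALSE),
    list(length = 30, distance = 5, dG = 7.5, pass = FALSE),
    list(length = 30, distance = 5, dG = 7.6, pass = TRUE))) {
    cand <- mk(case$length, case$distance, case$dG)
    expect_identical(cand$length, as.integer(case$length))
    expect_identical(cand$distance, as.integer(case$distance))
    expect_identical(passes_hairpin_rules(cand), case$pass)
  }
  # distance 3 cannot be represented inside the segment (it starts at
  # distance 4), so rule (ii) is checked on the lower edge via a
  # direct candidate with distance forced below range
  low <- mk(30, 4, 10)
  low$distance <- 3L
  expect_false(passes_hairpin_rules(low))

  # an A-U outermost pair fails rule (iii) even with a strong stem
  cand <- hairpin_candidate("AGCGCAAAAGCGCT", "(((((....)))))", -12)
  expect_false(cand$first_pair_gc)
  expect_false(passes_hairpin_rules(cand))
})

test_that("hairpin enumeration folds every truncation and deduplicates", {
  stem <- "GGCGACATCGCC"
  hp_seq <- make_hairpin_sequence(stem, "GAAA")   # 28 nt element
  # motif, the 3 nt preceding the segment, then the element at segment
  # offset 1 (-> distance 5)
  cds <- paste0(random_cds(40, seed = 5), "AAAAAAG", "CTC", "A", hp_seq,
                strrep("CAC", 30))
  motif_start <- 120L
  expect_identical(substr(cds, motif_start + 1, motif_start + 7), "AAAAAAG")

  # stub table: every prefix long enough to contain the element folds
  # into exactly the planted helix; shorter prefixes stay open
  seg0 <- segment_start0(motif_start, 7L)
  segment <- substr(cds, seg0 + 1, seg0 + 197)
  lens <- seq(nchar(segment), 17)
  struct_el <- make_hairpin_structure(12, 4)
  tab <- do.call(rbind, lapply(lens, function(L) {
    pre <- substr(segment, 1, L)
    if (L >= 1 + 28) {
      data.frame(seq = pre,
                 structure = paste0(".", struct_el,
                                    strrep(".", L - 29)),
                 energy = -14.2, stringsAsFactors = FALSE)
    } else {
      data.frame(seq = pre, structure = strrep(".", L), energy = 0,
                 stringsAsFactors = FALSE)
    }
  }))
  eng <- stub_engine(tab)
  out <- enumerate_hairpins(cds, motif_start, 7L, eng)
  expect_identical(nrow(out), 1L)  # identical triples deduplicated
  expect_identical(out$distance, 5L)
  expect_identical(out$length, 28L)
  expect_equal(out$dG_unfold, 14.2)

  # same element placed at distance 12 is rejected by the distance rule
  cds2 <- paste0(random_cds(40, seed = 5), "AAAAAAG", "CTC",
                 strrep("A", 8), hp_seq, strrep("CAC", 30))
  seg2 <- substr(cds2, seg0 + 1, seg0 + 197)
  lens2 <- seq(nchar(seg2), 17)
  tab2 <- do.call(rbind, lapply(lens2, function(L) {
    pre <- substr(seg2, 1, L)
    if (L >= 8 + 28) {
      data.frame(seq = pre,
                 structure = paste0(strrep(".", 8), struct_el,
                                    strrep(".", L - 36)),
                 energy = -14.2, stringsAsFactors = FALSE)
    } else {
      data.frame(seq = pre, structure = strrep(".", L), energy = 0,
                 stringsAsFactors = FALSE)
    }
  }))
  expect_identical(nrow(enumerate_hairpins(cds2, motif_start, 7L,
                                           stub_engine(tab2))), 0L)

  # a segment that never folds yields no candidates
  expect_identical(
    nrow(enumerate_hairpins(cds, motif_start, 7L,
                            stub_engine(tab[0, , drop = FALSE]))), 0L)
})

test_that("structure typing retains >= 50% types and scores the best", {
  cand <- function(length, distance, dgnt) {
    data.frame(distance = distance, length = length, structure = "x",
               dG_unfold = dgnt * length, dG_hp_per_nt = dgnt,
               first_pair_gc = TRUE, stacked_pairs_ok = TRUE,
               stringsAsFactors = FALSE)
  }
  # one type in all members: frequency 1, best
  ty <- group_structure_types(rep(list(cand(30, 5, 0.4)), 4))
  expect_equal(ty$frequency, 1)
  expect_identical(attr(ty, "best")$length, 30L)

  # type A freq 0.6 at 0.30 vs type B freq 0.9 at 0.25: B wins on score
  members <- c(rep(list(rbind(cand(30, 5, 0.30), cand(40, 6, 0.25))), 6),
               rep(list(cand(40, 6, 0.25)), 3),
               list(cand(99, 9, 0.9)))
  ty <- group_structure_types(members)
  expect_identical(attr(ty, "best")$length, 40L)
  expect_equal(attr(ty, "best")$score, 0.9 * 0.25)

  # frequency boundary: 0.49 dropped, 0.50 retained
  ty49 <- group_structure_types(c(rep(list(cand(30, 5, 0.4)), 49),
                                  rep(list(cand(30, 5, 0.4)[0, ]), 51)))
  expect_identical(nrow(ty49), 0L)
  ty50 <- group_structure_types(c(rep(list(cand(30, 5, 0.4)), 50),
                                  rep(list(cand(30, 5, 0.4)[0, ]), 50)))
  expect_identical(nrow(ty50), 1L)
})

test_that("ddG windows are counted and the identity case gives zero", {
  cds <- paste0(random_cds(20, seed = 2), "AAAAAAG", strrep("CAC", 70))
  motif_start <- 60L
  seg0 <- segment_start0(motif_start, 7L)
  segment <- substr(cds, seg0 + 1, seg0 + 197)
  w <- 24L
  starts <- seq_len(nchar(segment) - w + 1)
  tab <- data.frame(seq = substring(segment, starts, starts + w - 1),
                    structure = strrep(".", w), energy = -12,
                    stringsAsFactors = FALSE)
  dd <- compute_ddg(cds, motif_start, 7L, w, dG_hp_per_nt = 12 / w,
                    engine = stub_engine(tab))
  expect_identical(dd$n_windows, as.integer(nchar(segment) - w + 1))
  expect_equal(dd$ddG_per_nt, 0)
  expect_equal(dd$sd_window, 0)
  expect_false(dd$passes_is_threshold)

  expect_error(compute_ddg(cds, motif_start, 7L, 300, 0.5,
                           stub_engine(tab)), "segment")
})
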