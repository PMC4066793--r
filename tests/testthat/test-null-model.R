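shuffle_invariants_hold <- function(original, shuffled) {
  identical(translate_cds(shuffled), translate_cds(original)) &&
    identical(oracle_codon_multiset(shuffled),
              oracle_codon_multiset(original)) &&
    identical(as.vector(oracle_dinuc_counts(shuffled)),
              as.vector(oracle_dinuc_counts(original)))
}

test_that("degenerate sequences shuffle to themselves", {
  expect_identical(dicodon_shuffle("ATG"), "ATG")
  expect_identical(dicodon_shuffle("AAAAAA"), "AAAAAA")
  expect_error(dicodon_shuffle("ATGA"), "divisible")
})

test_that("dicodon shuffling preserves protein, codon usage and dinucleotides exactly", {
  set.seed(202)
  moved <- 0
  for (i in 1:100) {
    cds <- random_cds(sample(5:120, 1))
    sh <- dicodon_shuffle(cds)
    expect_true(shuffle_invariants_hold(cds, sh))
    expect_identical(substr(sh, 1, 3), substr(cds, 1, 3))  # start codon fixed
    if (sh != cds) moved <- moved + 1
  }
  expect_gt(moved, 50)  # the sampler does move most sequences
})

test_that("shuffle outputs lie in the exhaustively enumerated admissible set", {
  # ATG | CTA GCA CTG GCA | TAA: the two Leu codons can trade places
  # without touching any junction dinucleotide
  cds <- "ATGCTAGCACTGGCATAA"
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- strsplit(unname(translate_cds(cds)), "")[[1]]

  perms <- expand.grid(rep(list(2:5), 4))
  admissible <- character()
  for (r in seq_len(nrow(perms))) {
    idx <- as.integer(perms[r, ])
    if (any(sort(idx) != 2:5)) next
    cand <- paste(c(codons[1], codons[idx], codons[6]), collapse = "")
    ok <- identical(translate_cds(cand), translate_cds(cds)) &&
      identical(oracle_codon_multiset(cand), oracle_codon_multiset(cds)) &&
      identical(as.vector(oracle_dinuc_counts(cand)),
                as.vector(oracle_dinuc_counts(cds)))
    if (ok) admissible <- union(admissible, cand)
  }
  expect_gt(length(admissible), 1)

  set.seed(9)
  seen <- character()
  for (i in 1:200) seen <- union(seen, dicodon_shuffle(cds))
  expect_true(all(seen %in% admissible))
  expect_gt(length(seen), 1)
})

test_that("genome randomization is replicate-deterministic", {
  set.seed(4)
  genome <- setNames(vapply(1:6, function(i) random_cds(30), character(1)),
                     paste0("g", 1:6))
  r1 <- randomize_genome(genome, n_replicates = 2, seed = 7)
  r2 <- randomize_genome(genome, n_replicates = 2, seed = 7)
  expect_identical(r1, r2)
  expect_false(identical(r1[[1]], r1[[2]]))
  for (rep in r1) {
    for (id in names(genome))
      expect_true(shuffle_invariants_hold(genome[[id]], rep[[id]]))
    expect_identical(paste(translate_cds(rep), collapse = ""),
                     paste(translate_cds(genome), collapse = ""))
  }
  # the streaming count path sees the same replicates as the genome path
  pats <- enumerate_heptamers()
  ns <- null_frequency_summary(genome, pats, n_replicates = 3, seed = 7,
                               keep_replicates = TRUE)
  reps <- attr(ns, "replicates")
  cf <- count_motif_frequencies(r1[[1]], pats)
  expect_identical(unname(reps[, 1]),
                   cf$count[match(rownames(reps),
                                  paste(cf$pattern, cf$phase))])
})

test_that("z-scores follow the definition and flag degenerate cells", {
  obs <- data.frame(pattern = c("AAAAAAA", "AAAAAAC", "AAAAAAG"),
                    phase = 2L, count = c(8L, 10L, 5L))
  null <- data.frame(pattern = obs$pattern, phase = 2L,
                     x_mean = c(10, 10, 5), x_sd = c(2, 4, 0))
  z <- compute_zscores(obs, null)
  expect_equal(z$z[z$pattern == "AAAAAAA"], -1)
  expect_equal(z$z[z$pattern == "AAAAAAC"], 0)
  expect_true(z$undefined[z$pattern == "AAAAAAG"])
  expect_true(is.na(z$z[z$pattern == "AAAAAAG"]))
  expect_error(compute_zscores(obs, null[1:2, ]), "same")
})

test_that("null moments match the retained replicate counts", {
  set.seed(13)
  genome <- setNames(vapply(1:5, function(i) random_cds(40), character(1)),
                     paste0("g", 1:5))
  ns <- null_frequency_summary(genome, n_replicates = 25, seed = 3,
                               keep_replicates = TRUE)
  reps <- attr(ns, "replicates")
  key <- paste(ns$pattern, ns$phase)
  expect_equal(ns$x_mean, unname(rowMeans(reps)[key]))
  expect_equal(ns$x_sd, unname(apply(reps, 1, sd)[key]))
  expect_equal(ns$median, unname(apply(reps, 1, median)[key]))
})

test_that("efficiency-z correlation matches the closed-form Pearson formula", {
  z <- data.frame(pattern = enumerate_heptamers()[1:10], phase = 2L,
                  z = c(-2.1, -1.4, -0.2, 0.5, 1.1, -3.2, 0.9, -0.7, 2.2, 0.1),
                  undefined = FALSE)
  eff <- setNames(c(0.4, 0.2, 0.05, 0.3, 0.9, 0.12, 0.33, 0.08, 0.6, 0.25),
                  z$pattern)
  res <- efficiency_zscore_correlation(z, eff)
  x <- z$z; y <- unname(eff)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((10 - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = 8)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)

  # perfectly affine efficiencies give r = 1
  eff2 <- setNames(2 * x + 5, z$pattern)
  expect_equal(efficiency_zscore_correlation(z, eff2)$r, 1)
  expect_error(
    efficiency_zscore_correlation(z, setNames(rep(1, 10), z$pattern)),
    "variance")
})

test_that("candidate-motif selection applies the z and efficiency rule", {
  hepts <- enumerate_heptamers()
  z <- data.frame(pattern = hepts, phase = 2L, z = rep(1, 64),
                  undefined = FALSE)
  eff <- setNames(rep(0.5, 64), hepts)
  out <- select_candidate_motifs(z, eff, manual_add = c("CCCTTTC", "AAAGGGA"))
  expect_identical(unclass(out)[seq_along(out)],
                   sort(c("CCCTTTC", "AAAGGGA")))
  expect_length(attr(out, "base_set"), 0)

  # relaxing eff_min never removes a pattern
  z$z <- runif(64, -2, 2)
  s_strict <- select_candidate_motifs(z, eff, eff_min = 0.4)
  s_relaxed <- select_candidate_motifs(z, eff, eff_min = 0.1)
  expect_true(all(s_strict %in% s_relaxed))

  expect_error(select_candidate_motifs(z[-1, ], eff), "missing pattern")
})
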