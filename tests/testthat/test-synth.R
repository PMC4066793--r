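test_that("genome generation is deterministic and statistically on target", {
  g1 <- gen_genome(n_genes = 50, mean_codons = 80, seed = 5)
  g2 <- gen_genome(n_genes = 50, mean_codons = 80, seed = 5)
  expect_identical(g1, g2)
  expect_false(identical(g1, gen_genome(n_genes = 50, mean_codons = 80,
                                        seed = 6)))
  expect_true(all(vapply(g1, is_valid_cds, logical(1))))
  expect_true(all(substr(g1, 1, 3) == "ATG"))

  # realized internal-codon frequencies track the usage table within
  # a multinomial 3-sd envelope
  g <- gen_genome(n_genes = 400, mean_codons = 150, seed = 8)
  internal <- unlist(lapply(g, function(s) {
    cd <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cd[2:(length(cd) - 1)]
  }), use.names = FALSE)
  usage <- ecoli_codon_usage()
  sense <- setdiff(names(usage), c("TAA", "TAG", "TGA"))
  p <- usage[sense] / sum(usage[sense])
  n <- length(internal)
  obs <- table(factor(internal, levels = sense)) / n
  tol <- 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(obs - p) <= pmax(tol, 1e-4)))
})

test_that("dinucleotide-biased generation shifts junction composition", {
  g0 <- gen_genome(n_genes = 40, mean_codons = 80, dinuc_bias = 0, seed = 3)
  g1 <- gen_genome(n_genes = 40, mean_codons = 80, dinuc_bias = 0.9, seed = 3)
  cg <- function(g) {
    d <- Reduce(`+`, lapply(g, oracle_dinuc_counts))
    d[["CG"]] / sum(d)
  }
  expect_lt(cg(g1), cg(g0))  # the default target depletes CpG
  expect_true(all(vapply(g1, is_valid_cds, logical(1))))
})

test_that("pattern depletion removes hits synonymously", {
  g <- gen_genome(n_genes = 120, mean_codons = 120, seed = 12)
  d0 <- deplete_pattern(g, "AAAAAAA", fraction = 0, seed = 1)
  expect_identical(unname(unclass(d0)[seq_along(g)]), unname(g))

  d1 <- deplete_pattern(g, "AAAAAAA", fraction = 1, seed = 1)
  expect_gt(attr(d1, "n_initial"), 0)
  expect_identical(attr(d1, "n_remaining"), 0L)
  hits <- lapply(d1, function(s) {
    h <- scan_motifs(s, "AAAAAAA")
    h[h$phase == 2, ]
  })
  expect_identical(sum(vapply(hits, nrow, integer(1))), 0L)
  expect_identical(translate_cds(unname(unclass(d1)[seq_along(g)])),
                   translate_cds(unname(g)))

  dh <- deplete_pattern(g, "AAAAAAA", fraction = 0.5, seed = 2)
  expect_lt(attr(dh, "n_remaining"), attr(dh, "n_initial"))
})

test_that("cluster generation honours rate, conservation and jitter", {
  cl0 <- gen_cluster(n_members = 5, n_codons = 80, sub_rate = 0,
                     motif_codon = 30, seed = 4)
  expect_true(all(cl0$members == cl0$parent))
  expect_true(all(cl0$labels == "N1"))
  expect_identical(substr(cl0$parent, cl0$motif_start + 1,
                          cl0$motif_start + 7), cl0$motif)

  # divergence grows with the substitution rate
  div_at <- function(rate) {
    cl <- gen_cluster(n_members = 6, n_codons = 100, sub_rate = rate,
                      motif_codon = 30, seed = 7)
    mean(vapply(cl$members, function(m)
      mean(strsplit(m, "")[[1]] != strsplit(cl$parent, "")[[1]]),
      numeric(1)))
  }
  expect_lt(div_at(0.01), div_at(0.05))
  expect_lt(div_at(0.05), div_at(0.15))

  clj <- gen_cluster(n_members = 10, n_codons = 120, sub_rate = 0,
                     motif_codon = 40, n_jitter = 2, jitter_codons = 3,
                     seed = 5)
  expect_identical(sum(clj$labels == "N3"), 2L)
  expect_identical(sum(clj$labels == "N1"), 8L)
})

test_that("planted stimulators are recovered by the scanners", {
  cl <- gen_cluster(n_members = 1, n_codons = 120, motif_codon = 30,
                    sub_rate = 0, seed = 6)
  s <- cl$motif_start
  for (spacing in c(6, 10, 17)) {
    planted <- plant_stimulators(cl$parent, s, sd_pattern = "AGGA",
                                 sd_spacing = spacing, stem_bp = NULL)
    hits <- scan_sd(planted, s)
    expect_true(any(hits$sd_pattern == "AGGA" & hits$spacing == spacing))
  }
  # no-plant control on the same backbone
  bare <- scan_sd(cl$parent, s)
  expect_false(any(bare$sd_pattern == "AGGA" & bare$spacing == 10))
})

test_that("synthetic supplementary tables carry the planted marginal structure", {
  truth <- synthetic_assay_truth()
  prone <- attr(truth, "prone")
  sel <- attr(truth, "selection")
  expect_identical(lengths(prone), c(none = 39L, IS911 = 55L, IS3 = 61L))
  expect_true(all(prone$none %in% prone$IS911))
  expect_false(any(sel$is3_failures %in% prone$IS3))
  expect_true(all(c(sel$base18, sel$manual3) %in% prone$none))
  # efficiency floors used by the selection rule
  none <- truth[truth$context == "none", ]
  eff <- setNames(none$percent, none$motif)
  expect_true(all(eff[c(sel$base18, sel$manual3)] > 0.10))
  expect_true(all(eff[setdiff(names(eff), prone$none)] < 0.10))

  zt <- synthetic_zscore_table(seed = 2)
  expect_identical(nrow(zt), 192L)
  expect_equal(zt$z, (zt$x - zt$x_mean) / zt$x_sd)
  z2 <- zt[zt$phase == 2, ]
  neg <- z2$pattern[z2$z < 0]
  expect_true(all(sel$base18 %in% neg))
  expect_false(any(sel$manual3 %in% neg))
  for (ph in 0:2) {
    zp <- zt[zt$phase == ph, ]
    expect_lt(zp$z[zp$pattern == "AAAAAAA"], -2)
    expect_lt(zp$z[zp$pattern == "TTTTTTT"], -2)
  }
})
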