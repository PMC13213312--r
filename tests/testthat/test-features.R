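test_that("disorder odds ratio matches the reported arithmetic", {
  expect_equal(round(disorder_odds_ratio(0.53, 0.47, 0.322, 0.678), 1), 2.4)
  expect_equal(disorder_odds_ratio(0.4, 0.6, 0.4, 0.6), 1)
  expect_equal(disorder_odds_ratio(0.20, 0.80, 0.322, 0.678), 0.53,
               tolerance = 0.01)
  # equality of observed and expected gives 1 for any split
  for (p in c(0.1, 0.25, 0.7))
    expect_equal(disorder_odds_ratio(p, 1 - p, p, 1 - p), 1)
  expect_error(disorder_odds_ratio(0, 1, 0.3, 0.7), "strictly")
})

test_that("disorder and exposure proportions use the stated thresholds", {
  expect_equal(proportion_disordered(c(0.6, 0.4, 0.9, 0.5)), 0.5)  # 0.5 not >
  expect_equal(proportion_disordered(c(0.1, 0.2)), 0)
  expect_equal(proportion_disordered(c(0.6, 0.9)), 1)
  expect_error(proportion_disordered(numeric(0)), "empty")
  expect_equal(proportion_exposed(c(0.20, 0.19, 0.5, NA)), 2 / 3)  # >= 0.20
})

test_that("variant positional proportions report undefined, not zero", {
  lys <- data.frame(accession = "P1", position = 10L)
  variants <- data.frame(
    accession = "P1", position = c(rep(8L, 50), 10L, 12L),
    disease_associated = c(rep(c(TRUE, rep(FALSE, 9)), 5)[1:50] |
                             c(rep(TRUE, 3), rep(FALSE, 47)), TRUE, FALSE),
    synonymous = FALSE)
  # force exactly 3 disease of 50 at offset -2
  variants$disease_associated[1:50] <- c(rep(TRUE, 3), rep(FALSE, 47))
  out <- variant_position_proportions(lys, variants)
  expect_equal(out$proportion[out$offset == -2], 0.06)
  expect_equal(out$proportion[out$offset == 0], 1.0)
  expect_true(is.na(out$proportion[out$offset == 1]))   # no variants there
  expect_equal(out$proportion[out$offset == 2], 0)
  # synonymous variants are excluded before analysis
  syn <- variants; syn$synonymous <- TRUE
  out2 <- variant_position_proportions(lys, syn)
  expect_true(all(is.na(out2$proportion)))
})

test_that("proximity profile counts PTMs in the window", {
  lys <- data.frame(accession = "P1", position = 100L)
  phos <- data.frame(accession = "P1", position = c(92L, 111L))
  out <- proximity_profile(lys, phos, window = 10)
  expect_equal(out$n_nearby, 1L)  # 111 is outside
  expect_equal(out$frequency, 1)
  # no PTMs anywhere: all lysines in group 0
  none <- proximity_profile(lys, phos[0, ], window = 10)
  expect_equal(none$n_nearby, 0L)
  # a PTM at the lysine itself only counts with include_center
  ub <- data.frame(accession = "P1", position = 100L)
  expect_equal(proximity_profile(lys, ub, 10, include_center = TRUE)$n_nearby, 1L)
  expect_equal(proximity_profile(lys, ub, 10, include_center = FALSE)$n_nearby, 0L)
})

test_that("positional enrichment percentages sum to 100", {
  lys <- data.frame(accession = rep("P1", 2), position = c(50L, 80L))
  phos <- data.frame(accession = "P1", position = c(55L, 55L, 85L))
  out <- positional_enrichment(lys, phos, window = 10)
  expect_equal(sum(out$percent), 100)
  expect_equal(nrow(out), 20)  # center excluded
  expect_equal(out$percent[out$offset == 5], 100)  # all PTMs at +5
  out21 <- positional_enrichment(lys, phos, window = 10, include_center = TRUE)
  expect_equal(nrow(out21), 21)
  expect_error(positional_enrichment(lys, phos[0, ], 10), "no PTM")
})

test_that("flank extraction pads protein termini with X", {
  prot <- protein_record("P1", "MKDEAAKGLL")
  sites <- data.frame(accession = "P1", position = c(2L, 7L, 9L))
  fl <- extract_flanks(sites, prot)
  expect_identical(fl[1, ], c(`-2` = "X", `-1` = "M", `1` = "D", `2` = "E"))
  expect_identical(fl[2, ], c(`-2` = "A", `-1` = "A", `1` = "G", `2` = "L"))
  expect_identical(fl[3, ], c(`-2` = "K", `-1` = "G", `1` = "L", `2` = "X"))
})

test_that("flank enrichment normalizes to 1000 and divides by background", {
  # worked example: foreground at +1 {P:2, E:1, A:1}, background per-1000
  bg <- setNames(rep(NA_real_, 21), c(sort(names(aa_mass_table()$residue_mass)), "X"))
  bg[] <- 0; bg[c("P", "E", "A")] <- c(50, 70, 70)
  fl <- matrix(c("P", "P", "E", "A"), ncol = 1, dimnames = list(NULL, "1"))
  enr <- flank_enrichment(fl, bg)
  expect_equal(enr["P", "1"], (500 / 50))
  expect_equal(enr["E", "1"], (250 / 70))
  expect_true(is.na(enr["G", "1"]))  # absent from background -> undefined
  # per-position normalized counts sum to 1000
  expect_equal(sum(per1000_counts(fl[, 1])), 1000)
  # self-enrichment is exactly 1 for every present residue
  prot <- protein_record("P1", strrep("ACDEFGHIKLMNPQRSTVWY", 50))
  bg2 <- proteome_per1000(prot)
  res <- strsplit(prot$sequence, "")[[1]]
  fl2 <- matrix(res, ncol = 1, dimnames = list(NULL, "1"))
  enr2 <- flank_enrichment(fl2, bg2)
  expect_true(all(abs(enr2[!is.na(enr2[, 1]), 1] - 1) < 1e-9))
})

test_that("proteome background with offsets accrues X at termini", {
  prot <- protein_record(c("P1", "P2"), c("AAAA", "CCCC"))
  bg <- proteome_per1000(prot, offset = 2L)
  # for each 4-mer, positions 3 and 4 fall off the end: 2 of 4 are X
  expect_equal(unname(bg["X"]), 500)
  expect_equal(unname(bg["A"]), 250)
})

test_that("Bonferroni thresholds reproduce the stated divisors", {
  expect_equal(round(bonferroni_threshold(0.05, 84), 4), 6e-04)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  # the 252-comparison family: computed value, not the misprint
  expect_equal(bonferroni_threshold(0.05, 252), 0.000198, tolerance = 1e-3)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("pairwise chi-squared behaves at the contract's edges", {
  same <- chi2_pairwise(c(50, 50), c(100, 100))
  expect_gt(same$p_value, 0.99)
  diff <- chi2_pairwise(c(50, 50), c(90, 10))
  expect_lt(diff$p_value, 0.001)
  expect_error(chi2_pairwise(c(0, 10), c(0, 20)), "expected cell")
  # BH over 15 p-values preserves order and caps at 1
  set.seed(5)
  p <- runif(15)
  adj <- p.adjust(p, "BH")
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("motif variant enrichment agrees with the exact Fisher oracle", {
  sumo <- data.frame(motif = c("KxE", "DxK", "void"),
                     n_disease = c(8L, 4L, 0L), n_total = c(100L, 50L, 0L))
  nons <- data.frame(motif = c("KxE", "DxK", "void"),
                     n_disease = c(2L, 4L, 0L), n_total = c(100L, 50L, 0L))
  out <- motif_variant_enrichment(sumo, nons)
  kxe <- out[out$motif == "KxE", ]
  expect_equal(kxe$ratio, 4)
  expect_equal(kxe$p_value, oracle_fisher2x2(8, 92, 2, 98), tolerance = 1e-9)
  dxk <- out[out$motif == "DxK", ]
  expect_equal(dxk$ratio, 1)
  expect_gt(dxk$p_value, 0.99)
  expect_true(is.na(out$ratio[out$motif == "void"]))
  expect_true(is.na(out$p_adjusted[out$motif == "void"]))
})

test_that("Mann-Whitney matches exact permutation enumeration", {
  set.seed(3)
  for (i in 1:5) {
    x <- round(runif(4), 3)
    y <- round(runif(4) + 0.3, 3)
    got <- rasa_mann_whitney(x, y)
    expect_equal(got$p_value, oracle_mann_whitney(x, y), tolerance = 1e-9)
  }
})

test_that("structure elements resolve overlaps by fixed priority", {
  spans <- data.frame(accession = "P1",
                      start = c(1L, 5L, 5L), end = c(10L, 8L, 20L),
                      element = c("turn", "helix", "coiled_coil"))
  lys <- data.frame(accession = "P1", position = c(6L, 15L, 30L))
  expect_identical(structure_element(lys, spans),
                   c("helix", "coiled_coil", "none"))
})
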