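test_that("15-mer extraction pads termini and dedupes the foreground", {
  prot <- protein_record("P1", "AGTKAEGGQL")  # K at 4, length 10
  win <- extract_15mers(data.frame(accession = "P1", position = 4L), prot)
  expect_equal(nchar(win), 15L)
  expect_identical(win, "XXXXAGTKAEGGQLX")
  expect_identical(substring(win, 8, 8), "K")
  # identical windows collapse in the foreground
  prot2 <- protein_record(c("P1", "P2"), c("AGTKAEGGQL", "AGTKAEGGQL"))
  sites2 <- data.frame(accession = c("P1", "P2"), position = c(4L, 4L))
  expect_length(extract_15mers(sites2, prot2, dedupe = TRUE), 1)
  expect_length(extract_15mers(sites2, prot2, dedupe = FALSE), 2)
  # center residue enforced
  expect_error(extract_15mers(data.frame(accession = "P1", position = 5L), prot),
               "expected 'K'")
  # background covers every lysine, no dedupe
  bg <- background_15mers(prot2)
  expect_length(bg, 2)
})

test_that("motifx extracts a planted single-position motif with the closed-form p", {
  set.seed(21)
  other <- setdiff(names(human_aa_frequencies()), c("E", "K"))
  mk_win <- function(n, plus2 = NULL) {
    vapply(seq_len(n), function(i) {
      w <- sample(other, 15, replace = TRUE)
      w[8] <- "K"
      if (!is.null(plus2)) w[10] <- plus2
      paste(w, collapse = "")
    }, character(1))
  }
  fg <- mk_win(30, plus2 = "E")
  bg_e <- mk_win(30, plus2 = "E")
  bg_o <- mk_win(570)
  bg <- c(bg_e, bg_o)  # background E-at-+2 rate 0.05
  out <- motifx(fg, bg, min_occ = 25, p_max = 1e-6)
  expect_gte(nrow(out), 1)
  expect_identical(unname(out$fixed[[1]]["2"]), "E")
  expect_equal(out$fg_matches[1], 30)
  # first selection step: P(X >= 30 | 30, 0.05) = 0.05^30
  expect_equal(out$step_log_pvalues[[1]][1], 30 * log(0.05), tolerance = 1e-9)
  expect_lt(out$max_step_p[1], 1e-6)
  # empty / undersized foregrounds yield nothing
  expect_equal(nrow(motifx(mk_win(10), bg, min_occ = 25)), 0)
})

test_that("motifx agrees with the stepwise exhaustive oracle", {
  set.seed(77)
  residues <- sort(names(aa_mass_table()$residue_mass))
  for (trial in 1:6) {
    alph <- c("A", "G", "E")
    n_fg <- sample(c(60, 120, 200), 1)
    fg <- vapply(seq_len(n_fg), function(i) {
      w <- sample(alph, 15, replace = TRUE)
      w[8] <- "K"
      if (i <= n_fg * 0.4) w[10] <- "E"
      if (i <= n_fg * 0.2) w[7] <- "A"
      paste(w, collapse = "")
    }, character(1))
    bg <- vapply(1:400, function(i) {
      w <- sample(alph, 15, replace = TRUE)
      w[8] <- "K"
      paste(w, collapse = "")
    }, character(1))
    got <- motifx(fg, bg, min_occ = 10, p_max = 1e-4)
    want <- oracle_motifx(fg, bg, min_occ = 10, p_max = 1e-4, residues = residues)
    expect_identical(got$pattern, want,
                     label = sprintf("trial %d", trial))
  }
})

test_that("planted motif mixture is recovered with accurate enrichment", {
  set.seed(31)
  cfg <- sim_config(seed = 31, n_proteins = 80, n_sites = 400,
                    motif_mix = c(kxe = 0.45, dxk = 0.30))
  planted <- plant_sites(gen_proteome(cfg), cfg)
  fg <- extract_15mers(planted$sites, planted$proteome)
  bg <- background_15mers(planted$proteome)
  out <- motifx(fg, bg, min_occ = 25, p_max = 1e-6)
  pats <- vapply(out$fixed, classify_motif, character(1))
  expect_true("KxE" %in% pats)
  expect_true("DxK" %in% pats)
  # every emitted motif satisfies the occurrence and significance rules
  expect_true(all(out$fg_matches >= 25))
  expect_true(all(vapply(out$step_log_pvalues, max, numeric(1)) <= log(1e-6)))
  # the first extracted motif's fold agrees with a direct window count
  f1 <- out$fixed[[1]]
  direct_rate <- function(wins, f) {
    hit <- rep(TRUE, length(wins))
    for (off in names(f))
      hit <- hit & substring(wins, as.integer(off) + 8, as.integer(off) + 8) == f[[off]]
    mean(hit)
  }
  direct_fold <- direct_rate(fg, f1) / direct_rate(bg, f1)
  expect_equal(out$fold_enrichment[1], direct_fold, tolerance = 1e-9)
  # matching consistency: fg_matches equals windows matched by the map
  m <- do.call(rbind, strsplit(fg, ""))
  for (i in seq_len(nrow(out))) {
    f <- out$fixed[[i]]
    hit <- rep(TRUE, nrow(m))
    for (off in names(f)) hit <- hit & m[, as.integer(off) + 8] == f[[off]]
    # fg_matches is counted on the remaining pool, which is a subset
    expect_lte(out$fg_matches[i], sum(hit))
  }
})

test_that("motif classification follows the fixed precedence", {
  expect_identical(classify_motif(c(`-1` = "I", `2` = "E")), "KxE")
  expect_identical(classify_motif(c(`-2` = "E")), "ExK")
  expect_identical(classify_motif(c(`2` = "D")), "KxD")
  expect_identical(classify_motif(c(`-2` = "D", `1` = "P")), "DxK")
  expect_identical(classify_motif(c(`1` = "P")), "unique")
  # +2 E wins over -2 D
  expect_identical(classify_motif(c(`-2` = "D", `2` = "E")), "KxE")
})

test_that("adherence rate reproduces the printed Gold-set arithmetic", {
  fl <- matrix("G", nrow = 8639, ncol = 1, dimnames = list(NULL, "2"))
  fl[1:2485, 1] <- "E"
  expect_equal(adherence_rate(fl, 2, "E"), 2485 / 8639)
  expect_equal(round(100 * adherence_rate(fl, 2, "E")), 29)
  fl[] <- "G"
  expect_equal(adherence_rate(fl, 2, "E"), 0)
  fl[] <- "E"
  expect_equal(adherence_rate(fl, 2, "E"), 1)
})

test_that("motif hierarchy labels parents, children and orphans", {
  fixed <- list(c(`2` = "E"),
                c(`-1` = "L", `2` = "E"),
                c(`-2` = "D"))
  expect_identical(motif_hierarchy(fixed), c("parent", "child", "orphan"))
  expect_error(motif_hierarchy(list(c(`2` = "E"), c(`2` = "E"))), "duplicate")
  # same offsets, different residue: unrelated
  expect_identical(motif_hierarchy(list(c(`2` = "E"), c(`2` = "D"))),
                   c("orphan", "orphan"))
})

test_that("retention thresholds reproduce the printed counts", {
  expect_equal(retention_threshold(14623), 73L)
  expect_equal(retention_threshold(21098), 105L)
  expect_equal(retention_threshold(93341), 467L)
  expect_equal(retention_threshold(100), 1L)   # 0.5 rounds up (half-up)
  expect_equal(retention_threshold(1), 1L)     # floor of 1
  expect_equal(retention_threshold(300), 2L)   # 1.5 -> 2
})

test_that("motif TSV writer emits class and hierarchy", {
  set.seed(21)
  other <- setdiff(names(human_aa_frequencies()), c("E", "K"))
  fg <- vapply(1:40, function(i) {
    w <- sample(other, 15, TRUE); w[8] <- "K"; w[10] <- "E"
    paste(w, collapse = "")
  }, character(1))
  bg <- vapply(1:400, function(i) {
    w <- sample(c(other, "E"), 15, TRUE); w[8] <- "K"
    paste(w, collapse = "")
  }, character(1))
  out <- motifx(fg, bg)
  path <- tempfile(fileext = ".tsv")
  write_motif_tsv(out, path)
  back <- read.delim(path)
  expect_true(all(c("pattern", "class", "hierarchy") %in% names(back)))
  expect_identical(back$class[1], "KxE")
})
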