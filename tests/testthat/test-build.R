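mk_table <- function(acc, pos, flr, residue = "K", ds = "DS1",
                     cterm = FALSE) {
  data.frame(accession = acc, position = pos, residue = residue, flr = flr,
             dataset_id = ds, is_peptide_cterm = cterm,
             stringsAsFactors = FALSE)
}

test_that("parallel-search merging keeps the minimum FLR", {
  qq <- mk_table("P1", 10, 0.02)
  pyro <- mk_table("P1", 10, 0.008)
  merged <- merge_parallel_searches(list(qqtgg = qq, pyro = pyro), "DS1")
  expect_equal(nrow(merged), 1)
  expect_equal(merged$flr, 0.008)
  expect_identical(merged$searches, "pyro,qqtgg")
  # disjoint tables concatenate
  two <- merge_parallel_searches(list(mk_table("P1", 5, 0.01),
                                      mk_table("P2", 7, 0.02)), "DS1")
  expect_equal(nrow(two), 2)
  # idempotent on identical tables
  same <- merge_parallel_searches(list(qq, qq), "DS1")
  expect_equal(same$flr, qq$flr)
  expect_equal(nrow(same), 1)
  # residue conflict rejected
  bad <- mk_table("P1", 10, 0.01, residue = "A")
  expect_error(merge_parallel_searches(list(qq, bad), "DS1"), "conflicting")
})

test_that("the Asp-N C-terminal lysine rule keys on the following residue", {
  prot <- protein_record(c("P1", "P2", "P3"),
                         c("MAKDLL", "MAKGLL", "MAAAK"))
  sites <- rbind(mk_table("P1", 3, 0.01, cterm = TRUE),   # next residue D
                 mk_table("P2", 3, 0.01, cterm = TRUE),   # next residue G
                 mk_table("P2", 3, 0.01, cterm = FALSE),  # internal
                 mk_table("P3", 5, 0.01, cterm = TRUE))   # protein C-terminus
  out <- aspn_cterm_filter(sites, prot)
  expect_equal(nrow(out), 2)
  expect_true(all(out$accession %in% c("P1", "P2")))
  expect_identical(out$is_peptide_cterm, c(TRUE, FALSE))
  expect_error(aspn_cterm_filter(mk_table("P1", 99, 0.01, cterm = TRUE), prot),
               "beyond")
})

test_that("tier assignment reproduces the definitions", {
  tables <- list(
    rbind(mk_table("P1", 10, 0.005, ds = "DSA"),   # Gold: two sub-1%
          mk_table("P2", 20, 0.005, ds = "DSA"),   # Silver: one sub-1%
          mk_table("P3", 30, 0.03,  ds = "DSA")),  # Bronze
    rbind(mk_table("P1", 10, 0.009, ds = "DSB"),
          mk_table("P3", 30, 0.04,  ds = "DSB"),
          mk_table("P4", 40, 0.06,  ds = "DSB"))   # excluded: min 6%
  )
  build <- assign_tiers(tables)
  expect_equal(nrow(build), 3)
  tier <- setNames(build$tier, build$accession)
  expect_identical(tier[["P1"]], "Gold")
  expect_identical(tier[["P2"]], "Silver")
  expect_identical(tier[["P3"]], "Bronze")
  expect_false("P4" %in% build$accession)
  expect_equal(build$min_flr[build$accession == "P3"], 0.03)
})

test_that("parallel footprints within one dataset never count twice", {
  # the same site sub-1% in two searches of ONE dataset is Silver, not Gold
  t1 <- merge_parallel_searches(list(mk_table("P1", 10, 0.004),
                                     mk_table("P1", 10, 0.007)), "DS1")
  build <- assign_tiers(list(t1))
  expect_identical(build$tier, "Silver")
})

test_that("tiering matches the brute-force oracle on random FLR maps", {
  set.seed(99)
  n <- 2000
  tables <- list()
  truth <- character(n)
  for (i in seq_len(n)) {
    flrs <- random_flr_map(4)
    truth[i] <- oracle_tier(flrs)
    for (d in seq_along(flrs)) {
      tables[[length(tables) + 1L]] <-
        mk_table(sprintf("P%04d", i), 1L, flrs[d], ds = sprintf("DS%d", d))
    }
  }
  # group rows per dataset as the pipeline would supply them
  all <- do.call(rbind, tables)
  per_ds <- split(all, all$dataset_id)
  build <- assign_tiers(per_ds)
  got <- setNames(build$tier, build$accession)
  for (i in seq_len(n)) {
    acc <- sprintf("P%04d", i)
    if (is.na(truth[i])) expect_false(acc %in% names(got))
    else expect_identical(unname(got[acc]), truth[i], label = acc)
  }
  # partition invariant
  expect_equal(sum(build$tier %in% c("Gold", "Silver", "Bronze")), nrow(build))
})

test_that("recalculated set-level FLR reproduces the printed percentages", {
  expect_equal(recalculated_set_flr(46, 8639), 0.53)
  expect_equal(recalculated_set_flr(289, 22689), 1.27)
  expect_equal(recalculated_set_flr(2369, 35721), 6.63)
  expect_equal(recalculated_set_flr(0, 100), 0)
  expect_error(recalculated_set_flr(1, 0), "positive")
})

test_that("tier_set_flr aggregates cumulative sets", {
  build <- rbind(
    mk_build <- data.frame(accession = sprintf("P%d", 1:10), position = 1:10,
                           residue = c(rep("K", 8), "A", "A"),
                           min_flr = 0.004, n_datasets_sub1pct = 2L,
                           n_datasets = 2L, datasets = "a,b",
                           tier = c(rep("Gold", 4), rep("Silver", 3),
                                    "Bronze", "Gold", "Bronze"),
                           is_decoy = c(rep(FALSE, 8), TRUE, TRUE),
                           stringsAsFactors = FALSE))
  res <- tier_set_flr(build)
  expect_equal(res$n_target, c(4, 7, 8))
  expect_equal(res$n_decoy, c(1, 1, 2))
  expect_equal(res$flr_pct, c(25, 14.29, 25))
})

test_that("contaminant and decoy-site removal bookkeeps correctly", {
  build <- data.frame(accession = c("P1", "CONTAM_K", "P2", "P3"),
                      position = 1:4, residue = c("K", "K", "A", "K"),
                      min_flr = 0.001, n_datasets_sub1pct = 2L,
                      n_datasets = 2L, datasets = "a,b", tier = "Gold",
                      is_decoy = c(FALSE, FALSE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  res <- remove_contaminants_and_decoy_sites(build, "CONTAM_K")
  expect_equal(nrow(res$sites), 2)
  expect_equal(res$n_decoy, 1)
  expect_false(any(res$sites$is_decoy))
})

test_that("non-SUMO lysines exclude any candidate at any FLR", {
  peptides <- data.frame(
    peptide = c("AAKAA", "AAKAA", "KLKGG", "GGGGG"),
    protein_refs = c("P1", "P1", "P2", "P3"),
    peptide_starts = c("1", "1", "5", "1"),
    stringsAsFactors = FALSE)
  # P2 position 7 was once a SUMO candidate (at 40% FLR): excluded
  cand <- data.frame(accession = "P2", position = 7L)
  out <- build_nonsumo_set(peptides, cand)
  expect_true(all(paste(out$accession, out$position) %in%
                    c("P1 3", "P2 5")))
  expect_equal(out$evidence_count[out$accession == "P1"], 2L)
  # disjoint from the candidate set by construction
  expect_false(any(paste(out$accession, out$position) %in%
                     paste(cand$accession, cand$position)))
})

test_that("protein_site_table expands multi-mapped peptides", {
  sites <- data.frame(peptidoform = "AKA[2:471.21]", peptide = "AKA",
                      site_position = 2L, site_residue = "K",
                      dataset_id = "DS1", combined_probability = 0.99,
                      psm_count = 2L, protein_sites = "P1:5;P2:9",
                      is_decoy_site = FALSE, flr = 0.004,
                      stringsAsFactors = FALSE)
  tab <- protein_site_table(sites)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$position, c(5L, 9L))
  expect_true(all(tab$flr == 0.004))
})

test_that("build TSV round-trips", {
  build <- data.frame(accession = "P1", position = 3L, residue = "K",
                      min_flr = 0.002, n_datasets_sub1pct = 2L,
                      n_datasets = 3L, datasets = "a,b,c", tier = "Gold",
                      is_decoy = FALSE, stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_build_tsv(build, p)
  expect_equal(read_build_tsv(p), build)
})
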