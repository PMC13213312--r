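# Merging per-dataset site tables into the tiered SUMO build, the Asp-N
# C-terminal lysine rule, set-level FLR recalculation, and the
# non-SUMOylated reference lysine set.

#' Collapse peptidoform-sites to protein-coordinate sites for one dataset
#'
#' Expands the `protein_sites` multi-mapping (`acc:pos;acc:pos`), keys on
#' (accession, position) and keeps the minimum FLR per site.
#'
#' @param sites data.frame from [decoy_flr()].
#' @param dataset_id Dataset label stored on every row.
#' @return data.frame with `accession`, `position`, `residue`, `flr`,
#'   `dataset_id`, `is_peptide_cterm` (site at the peptide C-terminus in
#'   at least one supporting peptidoform at the minimal FLR).
#' @export
protein_site_table <- function(sites, dataset_id = sites$dataset_id[1]) {
  if (nrow(sites) == 0L)
    return(data.frame(accession = character(0), position = integer(0),
                      residue = character(0), flr = numeric(0),
                      dataset_id = character(0), is_peptide_cterm = logical(0),
                      stringsAsFactors = FALSE))
  maps <- strsplit(sites$protein_sites, ";", fixed = TRUE)
  n <- lengths(maps)
  long <- data.frame(map = unlist(maps),
                     residue = rep(sites$site_residue, n),
                     flr = rep(sites$flr, n),
                     cterm = rep(sites$site_position == nchar(sites$peptide), n),
                     stringsAsFactors = FALSE)
  parts <- strsplit(long$map, ":", fixed = TRUE)
  long$accession <- vapply(parts, `[`, "", 1L)
  long$position <- as.integer(vapply(parts, `[`, "", 2L))
  key <- paste(long$accession, long$position, sep = "\r")
  o <- order(long$flr)
  long <- long[o, , drop = FALSE]
  first <- !duplicated(paste(long$accession, long$position, sep = "\r"))
  out <- long[first, c("accession", "position", "residue", "flr", "cterm")]
  names(out)[names(out) == "cterm"] <- "is_peptide_cterm"
  out$dataset_id <- dataset_id
  rownames(out) <- NULL
  out[, c("accession", "position", "residue", "flr", "dataset_id",
          "is_peptide_cterm")]
}

#' Merge parallel footprint / digestion searches within one dataset
#'
#' Union keyed on (accession, position); the minimum FLR is kept and
#' provenance (which searches saw the site) recorded. Conflicting residue
#' identity at the same coordinate indicates coordinate corruption and is
#' rejected.
#'
#' @param tables List of protein-site data.frames from
#'   [protein_site_table()], one per parallel search.
#' @param dataset_id Dataset label for the merged table.
#' @return Merged site data.frame with a `searches` provenance column.
#' @export
merge_parallel_searches <- function(tables, dataset_id) {
  named <- names(tables)
  if (is.null(named)) named <- paste0("search", seq_along(tables))
  for (i in seq_along(tables)) tables[[i]]$search <- named[i]
  all <- do.call(rbind, tables)
  if (nrow(all) == 0L) {
    all$searches <- character(0)
    all$dataset_id <- character(0)
    return(all[, setdiff(names(all), "search")])
  }
  key <- paste(all$accession, all$position, sep = "\r")
  res_per_key <- tapply(all$residue, key, function(x) length(unique(x)))
  if (any(res_per_key > 1))
    stop("conflicting residue identity at the same protein coordinate")
  groups <- split(seq_len(nrow(all)), key)
  out <- lapply(groups, function(idx) {
    g <- all[idx, , drop = FALSE]
    best <- which.min(g$flr)
    data.frame(accession = g$accession[1], position = g$position[1],
               residue = g$residue[1], flr = min(g$flr),
               dataset_id = dataset_id,
               is_peptide_cterm = g$is_peptide_cterm[best],
               searches = paste(sort(unique(g$search)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Asp-N C-terminal lysine rule
#'
#' Asp-N cleaves N-terminal to D/E, so a lysine at a peptide C-terminus is
#' genuinely internal sequence, not a cleavage artifact - but a SUMOylated
#' C-terminal lysine is only plausible when the following protein residue
#' is D or E (otherwise cleavage there could not have produced the
#' observed peptide). Sites on peptide C-terminal lysines are kept iff
#' protein residue p+1 is D or E; a lysine at the protein C-terminus (no
#' p+1) is dropped. Internal sites pass through.
#'
#' @param sites Site data.frame with `is_peptide_cterm`.
#' @param proteins Protein data.frame (accession, sequence) for residue
#'   lookup.
#' @return Filtered site data.frame.
#' @export
aspn_cterm_filter <- function(sites, proteins) {
  if (nrow(sites) == 0L) return(sites)
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  keep <- vapply(seq_len(nrow(sites)), function(r) {
    if (!isTRUE(sites$is_peptide_cterm[r])) return(TRUE)
    s <- seqs[[sites$accession[r]]]
    if (is.null(s)) stop("unknown accession: ", sites$accession[r])
    p <- sites$position[r]
    if (p > nchar(s)) stop("site position beyond protein length")
    if (p == nchar(s)) return(FALSE)           # protein C-terminus: no p+1
    substring(s, p + 1L, p + 1L) %in% c("D", "E")
  }, logical(1))
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gold / Silver / Bronze confidence tiering across datasets
#'
#' Gold: the site passes FLR < 1% in two or more distinct datasets.
#' Silver: in exactly one dataset. Bronze: in none, but its minimum FLR
#' across datasets is below 5%. Sites with minimum FLR >= 5% are excluded.
#'
#' @param site_tables List of merged per-dataset site data.frames (from
#'   [merge_parallel_searches()] or [protein_site_table()]).
#' @param sub1 FLR cutoff defining a high-confidence observation (0.01).
#' @param keep_max Build-wide FLR cutoff (0.05), strict.
#' @return data.frame of build sites: `accession`, `position`, `residue`,
#'   `min_flr`, `n_datasets_sub1pct`, `n_datasets`, `datasets`, `tier`,
#'   `is_decoy`.
#' @export
assign_tiers <- function(site_tables, sub1 = 0.01, keep_max = 0.05) {
  all <- do.call(rbind, lapply(site_tables, function(t)
    t[, c("accession", "position", "residue", "flr", "dataset_id")]))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(accession = character(0), position = integer(0),
                      residue = character(0), min_flr = numeric(0),
                      n_datasets_sub1pct = integer(0), n_datasets = integer(0),
                      datasets = character(0), tier = character(0),
                      is_decoy = logical(0), stringsAsFactors = FALSE))
  key <- paste(all$accession, all$position, sep = "\r")
  groups <- split(seq_len(nrow(all)), key)
  out <- lapply(groups, function(idx) {
    g <- all[idx, , drop = FALSE]
    # one observation per dataset: the minimum FLR in that dataset
    per_ds <- tapply(g$flr, g$dataset_id, min)
    n_sub1 <- sum(per_ds < sub1)
    data.frame(accession = g$accession[1], position = g$position[1],
               residue = g$residue[1], min_flr = min(per_ds),
               n_datasets_sub1pct = n_sub1, n_datasets = length(per_ds),
               datasets = paste(sort(names(per_ds)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$min_flr < keep_max, , drop = FALSE]
  out$tier <- ifelse(out$n_datasets_sub1pct >= 2L, "Gold",
                     ifelse(out$n_datasets_sub1pct == 1L, "Silver", "Bronze"))
  out$is_decoy <- out$residue == "A"
  rownames(out) <- NULL
  out
}

#' Recalculated set-level FLR
#'
#' The percentage ratio of decoy-alanine site count to target lysine site
#' count within a tier set, reported to two decimal places.
#'
#' @param n_decoy Count of sites localized on the decoy amino acid.
#' @param n_target Count of lysine sites in the set.
#' @return Percentage rounded to 2 dp.
#' @export
recalculated_set_flr <- function(n_decoy, n_target) {
  if (n_target <= 0) stop("n_target must be positive")
  round(100 * n_decoy / n_target, 2)
}

#' Remove contaminant-protein sites and split off decoy-alanine sites
#'
#' @param sites Build site data.frame from [assign_tiers()].
#' @param contaminant_accessions Character vector of contaminant
#'   accessions (membership of the appended contaminant FASTA).
#' @return List with `sites` (clean lysine sites), `n_decoy` (alanine
#'   sites counted for set-level FLR, after contaminant removal).
#' @export
remove_contaminants_and_decoy_sites <- function(sites,
                                                contaminant_accessions = character(0)) {
  clean <- sites[!(sites$accession %in% contaminant_accessions), , drop = FALSE]
  n_decoy <- sum(clean$is_decoy)
  out <- clean[!clean$is_decoy, , drop = FALSE]
  rownames(out) <- NULL
  list(sites = out, n_decoy = n_decoy)
}

#' Set-level FLR per cumulative tier set
#'
#' Applies [recalculated_set_flr()] to the Gold, Gold-Silver and
#' Gold-Silver-Bronze cumulative sets of a tiered build (decoy-alanine
#' sites vs lysine sites).
#'
#' @param sites Tiered build data.frame (before decoy removal).
#' @return data.frame with `set`, `n_target`, `n_decoy`, `flr_pct`.
#' @export
tier_set_flr <- function(sites) {
  sets <- list(Gold = "Gold",
               `Gold-Silver` = c("Gold", "Silver"),
               `Gold-Silver-Bronze` = c("Gold", "Silver", "Bronze"))
  out <- lapply(names(sets), function(nm) {
    sub <- sites[sites$tier %in% sets[[nm]], , drop = FALSE]
    data.frame(set = nm,
               n_target = sum(!sub$is_decoy),
               n_decoy = sum(sub$is_decoy), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$flr_pct <- mapply(recalculated_set_flr, out$n_decoy, out$n_target)
  out
}

#' Construct the non-SUMOylated reference lysine set
#'
#' Takes every lysine covered by at least one FDR-retained peptide and
#' removes any lysine that appears in the uncut candidate-site expansion
#' of any dataset, at any FLR - the strictest reading of "not detected as
#' SUMOylated at any FLR threshold".
#'
#' @param peptides data.frame of FDR-retained peptide evidence with
#'   `peptide`, `protein_refs`, `peptide_starts` (`;`-separated parallel
#'   lists, as in the PSM table).
#' @param candidate_sites data.frame of all candidate protein sites (any
#'   FLR): needs `accession`, `position`.
#' @return data.frame: `accession`, `position`, `evidence_count`.
#' @export
build_nonsumo_set <- function(peptides, candidate_sites) {
  if (nrow(peptides) == 0L)
    return(data.frame(accession = character(0), position = integer(0),
                      evidence_count = integer(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(peptides)), function(r) {
    pep <- peptides$peptide[r]
    kpos <- which(strsplit(pep, "")[[1]] == "K")
    if (length(kpos) == 0L) return(NULL)
    accs <- strsplit(peptides$protein_refs[r], ";", fixed = TRUE)[[1]]
    starts <- as.integer(strsplit(peptides$peptide_starts[r], ";", fixed = TRUE)[[1]])
    do.call(rbind, lapply(seq_along(accs), function(i)
      data.frame(accession = accs[i], position = starts[i] + kpos - 1L,
                 stringsAsFactors = FALSE)))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(accession = character(0), position = integer(0),
                      evidence_count = integer(0), stringsAsFactors = FALSE))
  key <- paste(rows$accession, rows$position, sep = "\r")
  counts <- table(key)
  uniq <- rows[!duplicated(key), , drop = FALSE]
  uniq$evidence_count <- as.integer(counts[paste(uniq$accession, uniq$position,
                                                 sep = "\r")])
  sumo_key <- paste(candidate_sites$accession, candidate_sites$position, sep = "\r")
  out <- uniq[!(paste(uniq$accession, uniq$position, sep = "\r") %in% sumo_key), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read the build TSV
#'
#' @param build Build site data.frame.
#' @param path TSV path.
#' @export
write_build_tsv <- function(build, path) {
  utils::write.table(build, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_build_tsv
#' @export
read_build_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
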