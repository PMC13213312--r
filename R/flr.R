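# PSM-level FDR control, expansion to candidate modification sites,
# peptidoform-site collapsing, and decoy-amino-acid false localization
# rate (FLR) estimation. The decoy residue is alanine: SUMO cannot be
# conjugated to alanine, so any "localization" there is a counted error.

#' Target-decoy FDR filtering of PSMs
#'
#' PSMs are ranked by search score (descending, decoys before targets at
#' ties). The raw FDR at each rank is cumulative decoys over cumulative
#' targets, monotonized into q-values by a cumulative minimum from the
#' worst rank upward. Target PSMs with `q < q_max` are retained;
#' decoy-protein PSMs are dropped from the output.
#'
#' @param psms data.frame with at least `search_score` and
#'   `is_decoy_protein` columns.
#' @param q_max FDR cutoff (default 0.01), strict inequality.
#' @return The retained target PSMs with a `q_value` column.
#' @export
psm_fdr_filter <- function(psms, q_max = 0.01) {
  stopifnot(is.data.frame(psms), nrow(psms) > 0)
  if (!any(psms$is_decoy_protein))
    warning("no decoy-protein PSMs present; q-values are 0 everywhere")
  o <- order(-psms$search_score, !psms$is_decoy_protein)
  psms <- psms[o, , drop = FALSE]
  d <- cumsum(psms$is_decoy_protein)
  t <- cumsum(!psms$is_decoy_protein)
  raw <- ifelse(t == 0, 1, d / pmax(t, 1))
  q <- rev(cummin(rev(raw)))
  psms$q_value <- q
  out <- psms[!psms$is_decoy_protein & psms$q_value < q_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand FDR-filtered PSMs into candidate-site rows
#'
#' Each PSM carries per-candidate localization probabilities for the
#' searched modification. One row is emitted per (PSM, candidate site)
#' whose modification mass rounds to `footprint_mass_2dp` at two decimal
#' places. The PSM table encodes candidates in `site_prob_string` as
#' `pos:residue:prob` triplets separated by `;`, and the modification
#' masses in `mod_string` as `pos:mass` pairs.
#'
#' @param psms FDR-filtered PSM data.frame (columns `spectrum_ref`,
#'   `dataset_id`, `peptide`, `protein_refs`, `peptide_starts`,
#'   `mod_string`, `site_prob_string`).
#' @param footprint_mass_2dp Footprint delta mass rounded to 2 dp
#'   (e.g. `471.21`).
#' @return data.frame with one row per candidate site: `spectrum_ref`,
#'   `dataset_id`, `peptidoform`, `peptide`, `site_position`,
#'   `site_residue`, `probability`, `protein_refs`, `peptide_starts`.
#' @export
expand_sites <- function(psms, footprint_mass_2dp) {
  rows <- lapply(seq_len(nrow(psms)), function(r) {
    p <- psms[r, ]
    mods <- .parse_mod_string(p$mod_string)
    if (nrow(mods) == 0L) return(NULL)
    hit <- round(mods$mass, 2) == round(footprint_mass_2dp, 2)
    if (!any(hit)) return(NULL)
    cand <- .parse_site_probs(p$site_prob_string)
    if (nrow(cand) == 0L) return(NULL)
    peptidoform <- paste0(p$peptide, "[",
                          paste(sprintf("%d:%.2f", mods$position, mods$mass),
                                collapse = ","), "]")
    data.frame(spectrum_ref = p$spectrum_ref, dataset_id = p$dataset_id,
               peptidoform = peptidoform, peptide = p$peptide,
               site_position = cand$position, site_residue = cand$residue,
               probability = cand$probability,
               protein_refs = p$protein_refs, peptide_starts = p$peptide_starts,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    warning("footprint mass ", footprint_mass_2dp, " absent from all PSMs")
    rows <- data.frame(spectrum_ref = character(0), dataset_id = character(0),
                       peptidoform = character(0), peptide = character(0),
                       site_position = integer(0), site_residue = character(0),
                       probability = numeric(0), protein_refs = character(0),
                       peptide_starts = character(0), stringsAsFactors = FALSE)
  }
  rownames(rows) <- NULL
  rows
}

.parse_mod_string <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(position = integer(0), mass = numeric(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             mass = as.numeric(vapply(parts, `[`, "", 2L)))
}

.parse_site_probs <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(position = integer(0), residue = character(0),
                      probability = numeric(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             residue = vapply(parts, `[`, "", 2L),
             probability = as.numeric(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Combine redundant PSM probabilities for one site
#'
#' Multiple spectra observing the same peptidoform-site are redundant
#' evidence; the combined probability is `1 - prod(1 - p_i)`, capped at
#' 0.999999 so a single perfect observation cannot saturate the ranking.
#'
#' @param p Numeric vector of per-PSM localization probabilities.
#' @param cap Upper cap on the combined probability.
#' @return Combined probability.
#' @export
combine_site_probabilities <- function(p, cap = 0.999999) {
  stopifnot(all(p >= 0 & p <= 1))
  min(1 - prod(1 - p), cap)
}

#' Collapse candidate-site rows by peptidoform-site
#'
#' Groups rows on (peptidoform, site position), counts supporting PSMs and
#' combines their probabilities with [combine_site_probabilities()].
#' Protein-coordinate positions are expanded one per matched protein
#' (shared peptides multi-map).
#'
#' @param rows data.frame from [expand_sites()].
#' @param combiner Function reducing a probability vector to one value.
#' @return data.frame with one row per peptidoform-site: `peptidoform`,
#'   `peptide`, `site_position`, `site_residue`, `dataset_id`,
#'   `combined_probability`, `psm_count`, `protein_sites` (string
#'   `acc:pos` joined by `;`).
#' @export
collapse_peptidoform_sites <- function(rows, combiner = combine_site_probabilities) {
  if (nrow(rows) == 0L)
    return(data.frame(peptidoform = character(0), peptide = character(0),
                      site_position = integer(0), site_residue = character(0),
                      dataset_id = character(0), combined_probability = numeric(0),
                      psm_count = integer(0), protein_sites = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(rows$dataset_id, rows$peptidoform, rows$site_position, sep = "\r")
  groups <- split(seq_len(nrow(rows)), key)
  out <- lapply(groups, function(idx) {
    g <- rows[idx, , drop = FALSE]
    accs <- strsplit(g$protein_refs[1], ";", fixed = TRUE)[[1]]
    starts <- as.integer(strsplit(g$peptide_starts[1], ";", fixed = TRUE)[[1]])
    prot_sites <- paste(accs, starts + g$site_position[1] - 1L,
                        sep = ":", collapse = ";")
    data.frame(peptidoform = g$peptidoform[1], peptide = g$peptide[1],
               site_position = g$site_position[1],
               site_residue = g$site_residue[1],
               dataset_id = g$dataset_id[1],
               combined_probability = combiner(g$probability),
               psm_count = nrow(g), protein_sites = prot_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Decoy-amino-acid FLR estimation over ranked peptidoform-sites
#'
#' Sites are ranked by combined probability (descending; at exact
#' probability ties decoys sort first, conservatively). The raw FLR at
#' rank r is `scale * D_r / T_r` with cumulative decoy (alanine) and
#' target (lysine) counts; ranks before the first target have FLR 1. Ties
#' share the worst FLR of their tie group, and the column is monotonized
#' by a cumulative minimum from the worst rank upward.
#'
#' @param sites data.frame from [collapse_peptidoform_sites()] (needs
#'   `combined_probability` and `site_residue`).
#' @param scale Decoy scale factor; default 1 (no lysine:alanine
#'   frequency correction).
#' @param decoy_residue Decoy amino acid (default `"A"`).
#' @return `sites` sorted by rank with `is_decoy_site` and `flr` columns.
#' @export
decoy_flr <- function(sites, scale = 1.0, decoy_residue = "A") {
  if (nrow(sites) == 0L) {
    sites$is_decoy_site <- logical(0); sites$flr <- numeric(0)
    return(sites)
  }
  is_decoy <- sites$site_residue == decoy_residue
  o <- order(-sites$combined_probability, !is_decoy)
  sites <- sites[o, , drop = FALSE]
  is_decoy <- is_decoy[o]
  d <- cumsum(is_decoy)
  t <- cumsum(!is_decoy)
  raw <- ifelse(t == 0, 1, scale * d / pmax(t, 1))
  # ties share the worst (largest) FLR of the tie group
  tie_id <- match(sites$combined_probability, unique(sites$combined_probability))
  raw <- stats::ave(raw, tie_id, FUN = max)
  flr <- rev(cummin(rev(raw)))
  sites$is_decoy_site <- is_decoy
  sites$flr <- flr
  rownames(sites) <- NULL
  sites
}

#' Retain sites below an FLR cutoff
#'
#' Strict inequality; decoy sites passing the cut are retained (flagged)
#' for set-level FLR bookkeeping.
#'
#' @param sites data.frame with an `flr` column.
#' @param cut FLR cutoff (default 0.05).
#' @return Filtered data.frame.
#' @export
flr_threshold <- function(sites, cut = 0.05) {
  out <- sites[sites$flr < cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the FLR stage for one dataset
#'
#' Convenience wrapper: FDR-filter PSMs, expand candidate sites for the
#' footprint mass, collapse by peptidoform-site, estimate FLR.
#'
#' @param psms Raw PSM data.frame (see [read_psm_tsv()] for the schema).
#' @param footprint_mass_2dp Footprint mass at 2 dp.
#' @param q_max PSM FDR cutoff.
#' @param scale Decoy FLR scale factor.
#' @return List with `psms` (retained), `site_rows`, `sites` (with FLR).
#' @export
flr_pipeline <- function(psms, footprint_mass_2dp, q_max = 0.01, scale = 1.0) {
  kept <- psm_fdr_filter(psms, q_max = q_max)
  rows <- expand_sites(kept, footprint_mass_2dp)
  sites <- decoy_flr(collapse_peptidoform_sites(rows), scale = scale)
  list(psms = kept, site_rows = rows, sites = sites)
}

#' Read / write the PSM table TSV
#'
#' Columns: `spectrum_ref`, `dataset_id`, `peptide`, `protein_refs`,
#' `peptide_starts`, `search_score`, `is_decoy_protein`, `mod_string`,
#' `site_prob_string`.
#'
#' @param path TSV path.
#' @return data.frame of PSMs.
#' @export
read_psm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_decoy_protein <- as.logical(df$is_decoy_protein)
  for (col in c("peptide_starts", "protein_refs", "mod_string",
                "site_prob_string")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

#' @rdname read_psm_tsv
#' @param psms PSM data.frame.
#' @export
write_psm_tsv <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_psm_tsv
#' @param sites Peptidoform-site data.frame.
#' @export
write_site_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_psm_tsv
#' @export
read_site_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
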