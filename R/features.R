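# Structural, variant and PTM-proximity characterization of lysine sets.
# Thresholds follow the build conventions: disorder score > 0.5 (strict)
# is disordered, rASA >= 0.20 is exposed.

#' Odds ratio for disorder preference
#'
#' `OR = (p_dis_obs / p_dis_exp) / (p_ord_obs / p_ord_exp)` where the
#' observed proportions describe the lysine set and the expected
#' proportions the proteome background. Greater than 1 means a preference
#' for disordered regions.
#'
#' @param p_dis_obs,p_ord_obs Observed disordered/ordered proportions
#'   (must sum to 1).
#' @param p_dis_exp,p_ord_exp Expected background proportions.
#' @return The odds ratio.
#' @export
disorder_odds_ratio <- function(p_dis_obs, p_ord_obs, p_dis_exp, p_ord_exp) {
  p <- c(p_dis_obs, p_ord_obs, p_dis_exp, p_ord_exp)
  if (any(p <= 0 | p >= 1)) stop("all proportions must lie strictly in (0, 1)")
  (p_dis_obs / p_dis_exp) / (p_ord_obs / p_ord_exp)
}

#' Fraction of lysines in disordered regions
#'
#' @param scores Numeric per-lysine disorder scores in `[0, 1]`.
#' @param threshold Disorder threshold; strictly greater counts as
#'   disordered.
#' @return Fraction disordered.
#' @export
proportion_disordered <- function(scores, threshold = 0.5) {
  if (length(scores) == 0L) stop("empty lysine set")
  mean(scores > threshold)
}

#' Fraction of lysines classified as solvent-exposed
#'
#' @param rasa Numeric rASA values; `NA` entries are dropped.
#' @param threshold Exposure threshold (default 0.20, inclusive).
#' @return Fraction exposed.
#' @export
proportion_exposed <- function(rasa, threshold = 0.20) {
  rasa <- rasa[!is.na(rasa)]
  if (length(rasa) == 0L) stop("no rASA values")
  mean(rasa >= threshold)
}

#' Assign one secondary-structure element per lysine
#'
#' Span annotations may overlap; a fixed priority (helix > strand > turn >
#' coiled_coil) resolves the rare overlaps. Lysines in no span get
#' `"none"`.
#'
#' @param lysines data.frame with `accession`, `position`.
#' @param spans data.frame with `accession`, `start`, `end`, `element`.
#' @return Character vector of element labels, one per lysine.
#' @export
structure_element <- function(lysines, spans) {
  priority <- c("helix", "strand", "turn", "coiled_coil")
  vapply(seq_len(nrow(lysines)), function(r) {
    hit <- spans[spans$accession == lysines$accession[r] &
                 spans$start <= lysines$position[r] &
                 spans$end >= lysines$position[r], "element"]
    if (length(hit) == 0L) return("none")
    priority[min(match(hit, priority))]
  }, character(1))
}

#' Per-position proportions of disease-associated variants
#'
#' For relative positions -2..+2 around each lysine, the proportion of
#' disease-associated variants among all (non-synonymous) variants at
#' that position. Positions with no variants are `NA` (undefined), never
#' zero.
#'
#' @param lysines data.frame with `accession`, `position`.
#' @param variants data.frame with `accession`, `position`,
#'   `disease_associated`, `synonymous`.
#' @param offsets Relative positions (default `-2:2`).
#' @return data.frame with `offset`, `n_variants`, `n_disease`,
#'   `proportion`.
#' @export
variant_position_proportions <- function(lysines, variants, offsets = -2:2) {
  variants <- variants[!variants$synonymous, , drop = FALSE]
  out <- lapply(offsets, function(off) {
    key <- paste(lysines$accession, lysines$position + off, sep = "\r")
    vkey <- paste(variants$accession, variants$position, sep = "\r")
    hit <- variants[vkey %in% key, , drop = FALSE]
    n <- nrow(hit); nd <- sum(hit$disease_associated)
    data.frame(offset = off, n_variants = n, n_disease = nd,
               proportion = if (n > 0) nd / n else NA_real_)
  })
  do.call(rbind, out)
}

#' Distribution of lysines by count of nearby PTM sites
#'
#' Counts, for each lysine, the PTM sites on the same protein with
#' `|delta| <= window`; delta 0 is included only when `include_center`
#' (sensible for ubiquitin, which also targets lysine; impossible for
#' phosphosites). Returns the relative frequency of each count group.
#'
#' @param lysines data.frame with `accession`, `position`.
#' @param ptm_positions data.frame with `accession`, `position`.
#' @param window Window half-width in residues.
#' @param include_center Count a PTM at the lysine itself.
#' @return data.frame with `n_nearby`, `n_lysines`, `frequency`.
#' @export
proximity_profile <- function(lysines, ptm_positions, window = 10L,
                              include_center = FALSE) {
  ptm_by_acc <- split(ptm_positions$position, ptm_positions$accession)
  counts <- vapply(seq_len(nrow(lysines)), function(r) {
    p <- ptm_by_acc[[lysines$accession[r]]]
    if (is.null(p)) return(0L)
    d <- abs(p - lysines$position[r])
    sum(d <= window & (include_center | d > 0L))
  }, integer(1))
  tab <- table(counts)
  data.frame(n_nearby = as.integer(names(tab)),
             n_lysines = as.integer(tab),
             frequency = as.numeric(tab) / length(counts))
}

#' Positional enrichment of PTM sites around lysines
#'
#' For each relative position in the window, the percentage of all
#' in-window PTM observations falling at that position (summing to 100
#' over the profile).
#'
#' @inheritParams proximity_profile
#' @return data.frame with `offset`, `count`, `percent`.
#' @export
positional_enrichment <- function(lysines, ptm_positions, window = 10L,
                                  include_center = FALSE) {
  offs <- seq(-window, window)
  if (!include_center) offs <- offs[offs != 0L]
  ptm_by_acc <- split(ptm_positions$position, ptm_positions$accession)
  counts <- stats::setNames(rep(0L, length(offs)), offs)
  for (r in seq_len(nrow(lysines))) {
    p <- ptm_by_acc[[lysines$accession[r]]]
    if (is.null(p)) next
    d <- p - lysines$position[r]
    d <- d[abs(d) <= window & (include_center | d != 0L)]
    if (length(d)) {
      t <- table(factor(d, levels = offs))
      counts <- counts + as.integer(t)
    }
  }
  total <- sum(counts)
  if (total == 0L) stop("no PTM sites inside any window")
  data.frame(offset = offs, count = as.integer(counts),
             percent = 100 * as.integer(counts) / total)
}

#' Extract flanking residues around sites
#'
#' @param sites data.frame with `accession`, `position`.
#' @param proteins data.frame with `accession`, `sequence`.
#' @param offsets Flank offsets (default `c(-2, -1, 1, 2)`).
#' @return Character matrix, one row per site, one column per offset;
#'   positions beyond the protein termini are `"X"`.
#' @export
extract_flanks <- function(sites, proteins, offsets = c(-2L, -1L, 1L, 2L)) {
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  m <- matrix("X", nrow = nrow(sites), ncol = length(offsets),
              dimnames = list(NULL, as.character(offsets)))
  for (r in seq_len(nrow(sites))) {
    s <- seqs[[sites$accession[r]]]
    if (is.null(s)) stop("unknown accession: ", sites$accession[r])
    for (j in seq_along(offsets)) {
      p <- sites$position[r] + offsets[j]
      if (p >= 1L && p <= nchar(s)) m[r, j] <- substring(s, p, p)
    }
  }
  m
}

#' Per-1000 normalized residue counts
#'
#' Counts each of the 21 categories (20 residues plus `X` for a missing
#' flank) and scales so the counts sum to 1000.
#'
#' @param residues Character vector of residue symbols.
#' @return Named numeric vector over the 21 categories, summing to 1000.
#' @export
per1000_counts <- function(residues) {
  cats <- c(sort(names(aa_mass_table()$residue_mass)), "X")
  tab <- table(factor(residues, levels = cats))
  1000 * as.numeric(tab) / sum(tab) -> v
  stats::setNames(v, cats)
}

#' Flanking-residue enrichment relative to the proteome
#'
#' For each flank offset, foreground residue counts are normalized to a
#' total of 1000 and divided by the proteome's per-1000 value, fixing the
#' proteome at 1. Categories absent from the background are `NA`.
#'
#' @param flanks Character matrix from [extract_flanks()] (foreground).
#' @param background_per1000 Either a named per-1000 vector applied to all
#'   offsets, or a matrix with one column per offset.
#' @return Matrix of enrichment ratios (21 categories x offsets).
#' @export
flank_enrichment <- function(flanks, background_per1000) {
  if (nrow(flanks) == 0L) stop("empty lysine set")
  cats <- c(sort(names(aa_mass_table()$residue_mass)), "X")
  out <- sapply(colnames(flanks), function(cn) {
    fg <- per1000_counts(flanks[, cn])
    bg <- if (is.matrix(background_per1000)) background_per1000[, cn]
          else background_per1000
    bg <- bg[cats]
    ifelse(is.na(bg) | bg == 0, NA_real_, fg[cats] / bg)
  })
  rownames(out) <- cats
  out
}

#' Proteome background per-1000 residue composition
#'
#' The plain residue composition of the proteome, per 1000 residues, with
#' the `X` category filled from flank positions that fall off protein
#' termini when `offsets` are supplied (the same accounting as the
#' foreground windows).
#'
#' @param proteins data.frame with `sequence`.
#' @param offset Optional flank offset; when given, the composition is
#'   computed over the flank at that offset around every residue, so
#'   off-terminus positions contribute `X` counts.
#' @return Named per-1000 vector over the 21 categories.
#' @export
proteome_per1000 <- function(proteins, offset = NULL) {
  if (is.null(offset)) {
    res <- strsplit(paste(proteins$sequence, collapse = ""), "")[[1]]
    return(per1000_counts(res))
  }
  res <- unlist(lapply(proteins$sequence, function(s) {
    n <- nchar(s)
    p <- seq_len(n) + offset
    out <- rep("X", n)
    ok <- p >= 1L & p <= n
    out[ok] <- substring(s, p[ok], p[ok])
    out
  }))
  per1000_counts(res)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of comparisons, at least 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Pairwise chi-squared test on count tables
#'
#' Standard chi-squared test of independence (without continuity
#' correction) on the 2 x k table formed by stacking two count vectors.
#' Zero expected cells are rejected with guidance to pool categories.
#'
#' @param counts_a,counts_b Non-negative integer count vectors of equal
#'   length.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_pairwise <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  tab <- rbind(counts_a, counts_b)
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp == 0))
    stop("zero expected cell count; pool categories before testing")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Disease-variant enrichment within motifs
#'
#' For each motif group, the enrichment ratio is the proportion of
#' disease-associated variants at SUMOylated lysines over the proportion
#' at non-SUMOylated lysines, with a Fisher exact test on the 2 x 2
#' (disease vs non-disease by SUMO vs non-SUMO) and Benjamini-Hochberg
#' adjustment across motifs. Motifs with no variants in either set are
#' reported with `NA` ratio and excluded from adjustment.
#'
#' @param sumo_counts,nonsumo_counts data.frames with `motif`, `n_disease`,
#'   `n_total` (variant counts at the lysine residue only).
#' @return data.frame with per-motif `ratio`, `p_value`, `p_adjusted`.
#' @export
motif_variant_enrichment <- function(sumo_counts, nonsumo_counts) {
  merged <- merge(sumo_counts, nonsumo_counts, by = "motif",
                  suffixes = c("_sumo", "_nonsumo"))
  res <- lapply(seq_len(nrow(merged)), function(r) {
    g <- merged[r, ]
    defined <- g$n_total_sumo > 0 && g$n_total_nonsumo > 0
    ratio <- if (defined && g$n_disease_nonsumo > 0)
      (g$n_disease_sumo / g$n_total_sumo) /
        (g$n_disease_nonsumo / g$n_total_nonsumo)
    else NA_real_
    p <- if (defined) stats::fisher.test(matrix(c(
      g$n_disease_sumo, g$n_total_sumo - g$n_disease_sumo,
      g$n_disease_nonsumo, g$n_total_nonsumo - g$n_disease_nonsumo),
      nrow = 2, byrow = TRUE))$p.value else NA_real_
    data.frame(motif = g$motif, ratio = ratio, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- NA_real_
  ok <- !is.na(res$p_value)
  res$p_adjusted[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
  res
}

#' Two-sided Mann-Whitney comparison of rASA distributions
#'
#' Contract over the standard routine; exact for small samples without
#' ties.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (U for `x`), `p_value`.
#' @export
rasa_mann_whitney <- function(x, y) {
  ht <- stats::wilcox.test(x, y, alternative = "two.sided", exact = NULL)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
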