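# SUMO / ubiquitin crosstalk: lysines modified by one, the other, or both.

#' Partition lysines by SUMO / ubiquitin modification status
#'
#' Set algebra on (accession, position): sites in both builds are
#' `SUMO-Ub`, the rest `SUMO-unique` or `Ub-unique`. Duplicate
#' coordinates within one build are collapsed with a warning.
#'
#' @param sumo_sites,ub_sites data.frames with `accession`, `position`
#'   (a `tier` column, if present, is carried through).
#' @return data.frame with `accession`, `position`, `category`,
#'   `sumo_tier`, `ub_tier`.
#' @export
classify_overlap <- function(sumo_sites, ub_sites) {
  dedupe <- function(df, label) {
    key <- paste(df$accession, df$position, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate coordinates in ", label, " build collapsed")
      df <- df[!duplicated(key), , drop = FALSE]
    }
    df
  }
  sumo_sites <- dedupe(sumo_sites, "SUMO")
  ub_sites <- dedupe(ub_sites, "ubiquitin")
  skey <- paste(sumo_sites$accession, sumo_sites$position, sep = "\r")
  ukey <- paste(ub_sites$accession, ub_sites$position, sep = "\r")
  stier <- if ("tier" %in% names(sumo_sites)) sumo_sites$tier else NA_character_
  utier <- if ("tier" %in% names(ub_sites)) ub_sites$tier else NA_character_
  both <- intersect(skey, ukey)
  mk <- function(keys, category) {
    if (length(keys) == 0L)
      return(data.frame(accession = character(0), position = integer(0),
                        category = character(0), sumo_tier = character(0),
                        ub_tier = character(0), stringsAsFactors = FALSE))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(accession = vapply(parts, `[`, "", 1L),
               position = as.integer(vapply(parts, `[`, "", 2L)),
               category = category,
               sumo_tier = if (length(stier) > 1 || !is.na(stier[1]))
                 ifelse(keys %in% skey, stier[match(keys, skey)], NA_character_)
               else NA_character_,
               ub_tier = if (length(utier) > 1 || !is.na(utier[1]))
                 ifelse(keys %in% ukey, utier[match(keys, ukey)], NA_character_)
               else NA_character_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(setdiff(skey, ukey), "SUMO-unique"),
               mk(both, "SUMO-Ub"),
               mk(setdiff(ukey, skey), "Ub-unique"))
  rownames(out) <- NULL
  out
}

#' Category counts of an overlap partition
#'
#' @param overlap data.frame from [classify_overlap()].
#' @return Named integer vector over the three categories.
#' @export
overlap_counts <- function(overlap) {
  cats <- c("SUMO-unique", "SUMO-Ub", "Ub-unique")
  tab <- table(factor(overlap$category, levels = cats))
  stats::setNames(as.integer(tab), cats)
}

#' Run the comparative feature analyses per overlap category
#'
#' Reuses the feature-module operations per category: disorder proportion
#' against the proteome background, secondary-structure proportions,
#' variant positional proportions (with pairwise chi-squared over the 15
#' position-by-comparison tests, BH-adjusted), and motif extraction with
#' the per-set retention threshold. Empty categories are skipped with a
#' warning.
#'
#' @param overlap data.frame from [classify_overlap()].
#' @param annotations List with elements `disorder` (accession, position,
#'   score), `spans`, `variants`, and optionally `proteins` (needed for
#'   motif extraction).
#' @param background_disorder Proteome background disorder proportion.
#' @param run_motifs Extract motifs per category (needs `proteins` and a
#'   background window set in `annotations$background_windows`).
#' @return Named list of per-category reports plus `variant_tests`.
#' @export
run_category_analyses <- function(overlap, annotations,
                                  background_disorder = 0.322,
                                  run_motifs = FALSE) {
  cats <- c("SUMO-unique", "Ub-unique", "SUMO-Ub")
  dis_key <- paste(annotations$disorder$accession,
                   annotations$disorder$position, sep = "\r")
  reports <- list()
  for (cat in cats) {
    sub <- overlap[overlap$category == cat, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("empty category: ", cat)
      next
    }
    rep <- list(n_sites = nrow(sub))
    idx <- match(paste(sub$accession, sub$position, sep = "\r"), dis_key)
    scores <- annotations$disorder$score[idx]
    scores <- scores[!is.na(scores)]
    if (length(scores)) {
      p_dis <- proportion_disordered(scores)
      n <- length(scores)
      rep$disorder <- list(
        proportion = p_dis,
        vs_background = chi2_pairwise(
          c(round(n * p_dis), n - round(n * p_dis)),
          c(round(n * background_disorder),
            n - round(n * background_disorder))))
    }
    if (!is.null(annotations$spans)) {
      el <- structure_element(sub, annotations$spans)
      rep$structure <- prop.table(table(factor(
        el, levels = c("helix", "strand", "turn", "coiled_coil", "none"))))
    }
    if (!is.null(annotations$variants))
      rep$variants <- variant_position_proportions(sub, annotations$variants)
    if (run_motifs && !is.null(annotations$proteins)) {
      fg <- extract_15mers(sub, annotations$proteins)
      thr <- retention_threshold(nrow(sub))
      mots <- motifx(fg, annotations$background_windows)
      rep$motifs <- mots[mots$fg_matches >= thr, , drop = FALSE]
    }
    reports[[cat]] <- rep
  }
  # 15 pairwise variant tests: 5 positions x 3 category pairs, BH-adjusted
  present <- intersect(cats, names(reports))
  pairs <- if (length(present) >= 2)
    utils::combn(present, 2, simplify = FALSE) else list()
  tests <- list()
  for (pr in pairs) {
    va <- reports[[pr[1]]]$variants; vb <- reports[[pr[2]]]$variants
    if (is.null(va) || is.null(vb)) next
    for (i in seq_len(nrow(va))) {
      ok <- va$n_variants[i] > 0 && vb$n_variants[i] > 0 &&
        (va$n_disease[i] + vb$n_disease[i]) > 0 &&
        (va$n_variants[i] - va$n_disease[i] + vb$n_variants[i] - vb$n_disease[i]) > 0
      p <- if (ok) chi2_pairwise(
        c(va$n_disease[i], va$n_variants[i] - va$n_disease[i]),
        c(vb$n_disease[i], vb$n_variants[i] - vb$n_disease[i]))$p_value
      else NA_real_
      tests[[length(tests) + 1L]] <- data.frame(
        comparison = paste(pr, collapse = " vs "), offset = va$offset[i],
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(tests)) {
    tests <- do.call(rbind, tests)
    ok <- !is.na(tests$p_value)
    tests$p_adjusted <- NA_real_
    tests$p_adjusted[ok] <- stats::p.adjust(tests$p_value[ok], method = "BH")
    reports$variant_tests <- tests
  }
  reports
}
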