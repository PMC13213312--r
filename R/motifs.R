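# Iterative motif-x style extraction of overrepresented motifs from
# K-centered 15-mers. The binomial upper tail is evaluated in log space
# so step p-values remain ordered down to ~1e-300.

#' Extract K-centered 15-mers around sites
#'
#' Each window spans seven residues on either side of the central lysine;
#' positions beyond the protein termini are padded with `X`. Foreground
#' windows are deduplicated on the window string; backgrounds (every
#' lysine in the proteome) are not.
#'
#' @param sites data.frame with `accession`, `position`.
#' @param proteins data.frame with `accession`, `sequence`.
#' @param dedupe Deduplicate identical windows (foreground rule).
#' @param center_residue Required central residue; rows whose center is
#'   not this residue are rejected.
#' @param flank Residues on each side (default 7, giving 15-mers).
#' @return Character vector of windows.
#' @export
extract_15mers <- function(sites, proteins, dedupe = TRUE,
                           center_residue = "K", flank = 7L) {
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  win <- vapply(seq_len(nrow(sites)), function(r) {
    s <- seqs[[sites$accession[r]]]
    if (is.null(s)) stop("unknown accession: ", sites$accession[r])
    p <- sites$position[r]
    center <- substring(s, p, p)
    if (center != center_residue)
      stop("window center at ", sites$accession[r], ":", p,
           " is '", center, "', expected '", center_residue, "'")
    idx <- (p - flank):(p + flank)
    chars <- rep("X", length(idx))
    ok <- idx >= 1L & idx <= nchar(s)
    chars[ok] <- substring(s, idx[ok], idx[ok])
    paste(chars, collapse = "")
  }, character(1))
  if (dedupe) win <- unique(win)
  win
}

#' Background 15-mers over every central-residue position in a proteome
#'
#' @inheritParams extract_15mers
#' @return Character vector of windows (not deduplicated).
#' @export
background_15mers <- function(proteins, center_residue = "K", flank = 7L) {
  sites <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(r) {
    pos <- which(strsplit(proteins$sequence[r], "")[[1]] == center_residue)
    if (length(pos) == 0L) return(NULL)
    data.frame(accession = proteins$accession[r], position = pos,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sites)) return(character(0))
  extract_15mers(sites, proteins, dedupe = FALSE,
                 center_residue = center_residue, flank = flank)
}

.window_matrix <- function(windows) {
  if (length(windows) == 0L) return(matrix(character(0), nrow = 0))
  do.call(rbind, strsplit(windows, ""))
}

# log-space binomial upper tail P(X >= k | n, p)
.binom_tail_log <- function(k, n, p) {
  if (k <= 0) return(0)                      # log(1)
  if (p <= 0) return(-Inf)
  if (p >= 1) return(0)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE)
}

#' Iterative motif-x extraction
#'
#' At each step, every (offset, residue) pair is scored by the binomial
#' upper tail of its foreground count against the background frequency at
#' that offset; the most significant pair meeting both the significance
#' and the occurrence thresholds is fixed and both pools are reduced to
#' matching windows. When no pair qualifies the motif is emitted, its
#' matched foreground windows leave the pool, the background is restored
#' in full, and extraction restarts for the next motif.
#'
#' Ties in step selection break deterministically: lowest p-value, then
#' highest count, then smallest absolute offset, then lexicographic
#' residue. `X` never matches and is excluded from frequency denominators.
#'
#' @param fg,bg Character vectors of equal-length windows (foreground is
#'   typically deduplicated, background not).
#' @param min_occ Minimum foreground occurrences for a fixable pair.
#' @param p_max Significance threshold on each step p-value.
#' @return data.frame of motifs: `pattern` (dotted string), `fixed`
#'   (offset:residue list-column), `fg_matches`, `fg_total`, `bg_matches`,
#'   `bg_total`, `fold_enrichment`, `step_log_pvalues` (list-column),
#'   `max_step_p`.
#' @export
motifx <- function(fg, bg, min_occ = 25L, p_max = 1e-6) {
  stopifnot(length(fg) > 0L, length(bg) > 0L)
  width <- nchar(fg[1])
  stopifnot(all(nchar(fg) == width), all(nchar(bg) == width))
  center <- (width + 1L) %/% 2L
  offsets <- seq_len(width) - center
  fg_m <- .window_matrix(fg)
  bg_m0 <- .window_matrix(bg)
  residues <- sort(names(aa_mass_table()$residue_mass))
  motifs <- list()
  repeat {
    sel <- .motifx_one(fg_m, bg_m0, center, min_occ, p_max, residues)
    if (is.null(sel)) break
    motifs[[length(motifs) + 1L]] <- sel$motif
    fg_m <- fg_m[!sel$fg_matched, , drop = FALSE]
    if (nrow(fg_m) < min_occ) break
  }
  if (length(motifs) == 0L)
    return(data.frame(pattern = character(0), fg_matches = integer(0),
                      fg_total = integer(0), bg_matches = integer(0),
                      bg_total = integer(0), fold_enrichment = numeric(0),
                      max_step_p = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(motifs, `[[`, "row"))
  out$fixed <- lapply(motifs, `[[`, "fixed")
  out$step_log_pvalues <- lapply(motifs, `[[`, "steps")
  rownames(out) <- NULL
  out
}

# one motif extraction pass; returns NULL when no motif can be seeded
.motifx_one <- function(fg_m, bg_m, center, min_occ, p_max, residues) {
  fg_pool <- rep(TRUE, nrow(fg_m))
  bg_pool <- rep(TRUE, nrow(bg_m))
  fixed <- integer(0)       # named: offset -> residue
  fixed_res <- character(0)
  steps <- numeric(0)
  width <- ncol(fg_m)
  offsets <- seq_len(width) - center
  fg_total <- nrow(fg_m)
  bg_total <- nrow(bg_m)
  repeat {
    best <- NULL
    n_fg <- sum(fg_pool)
    for (col in seq_len(width)) {
      if (col == center || (length(fixed) && col %in% fixed)) next
      fg_col <- fg_m[fg_pool, col]
      bg_col <- bg_m[bg_pool, col]
      bg_nonx <- bg_col[bg_col != "X"]
      if (length(bg_nonx) == 0L) next
      bg_tab <- table(factor(bg_nonx, levels = residues))
      fg_tab <- table(factor(fg_col, levels = residues))
      for (res in residues) {
        k <- fg_tab[[res]]
        if (k < min_occ) next
        p <- bg_tab[[res]] / length(bg_nonx)
        lp <- .binom_tail_log(k, n_fg, p)
        if (lp > log(p_max)) next
        cand <- list(col = col, res = res, k = k, lp = lp,
                     abs_off = abs(offsets[col]))
        if (is.null(best) ||
            lp < best$lp ||
            (lp == best$lp && (k > best$k ||
              (k == best$k && (cand$abs_off < best$abs_off ||
                (cand$abs_off == best$abs_off && res < best$res))))))
          best <- cand
      }
    }
    if (is.null(best)) break
    fixed <- c(fixed, best$col)
    fixed_res <- c(fixed_res, best$res)
    steps <- c(steps, best$lp)
    fg_pool <- fg_pool & fg_m[, best$col] == best$res
    bg_pool <- bg_pool & bg_m[, best$col] == best$res
  }
  if (length(fixed) == 0L) return(NULL)
  fg_matched <- rep(TRUE, nrow(fg_m))
  bg_matched <- rep(TRUE, nrow(bg_m))
  for (i in seq_along(fixed)) {
    fg_matched <- fg_matched & fg_m[, fixed[i]] == fixed_res[i]
    bg_matched <- bg_matched & bg_m[, fixed[i]] == fixed_res[i]
  }
  fg_k <- sum(fg_matched); bg_k <- sum(bg_matched)
  pattern <- rep(".", width)
  pattern[center] <- "K"
  pattern[fixed] <- fixed_res
  fixed_map <- stats::setNames(fixed_res, offsets[fixed])
  fold <- (fg_k / fg_total) / (bg_k / bg_total)
  list(motif = list(
         row = data.frame(pattern = paste(pattern, collapse = ""),
                          fg_matches = fg_k, fg_total = fg_total,
                          bg_matches = bg_k, bg_total = bg_total,
                          fold_enrichment = fold,
                          max_step_p = exp(max(steps)),
                          stringsAsFactors = FALSE),
         fixed = fixed_map, steps = steps),
       fg_matched = fg_matched)
}

#' Classify a motif into the canonical SUMO motif families
#'
#' Precedence: E at +2 (KxE-type), else E at -2 (ExK-type), else D at +2
#' (KxD-type), else D at -2 (DxK-type), else unique.
#'
#' @param fixed Named character vector mapping offsets (as names, e.g.
#'   `"-2"`, `"2"`) to residues.
#' @return One of `"KxE"`, `"ExK"`, `"KxD"`, `"DxK"`, `"unique"`.
#' @export
classify_motif <- function(fixed) {
  at <- function(off) {
    v <- fixed[as.character(off)]
    if (length(v) == 0L || is.na(v)) "" else unname(v)
  }
  if (at(2) == "E") "KxE"
  else if (at(-2) == "E") "ExK"
  else if (at(2) == "D") "KxD"
  else if (at(-2) == "D") "DxK"
  else "unique"
}

#' Fraction of sites matching a core offset/residue constraint
#'
#' @param flanks Character matrix from [extract_flanks()] (columns named
#'   by offset) or of windows; or a data.frame of sites with an
#'   offset-named column.
#' @param offset Offset of the constraint (e.g. `2` for the canonical
#'   K-x-E core).
#' @param residue Required residue at the offset.
#' @return Fraction of rows matching.
#' @export
adherence_rate <- function(flanks, offset, residue) {
  col <- as.character(offset)
  if (!col %in% colnames(flanks)) stop("offset ", offset, " not in flank matrix")
  if (nrow(flanks) == 0L) return(0)
  mean(flanks[, col] == residue)
}

#' Parent / child / orphan labels for a motif set
#'
#' Motif A is a parent of B when A's fixed constraints are a strict subset
#' of B's (same residues at shared offsets). A motif with an ancestor is a
#' child; one with descendants but no ancestor is a parent; the rest are
#' orphans. Duplicate fixed maps are rejected.
#'
#' @param fixed_list List of named character vectors (offset -> residue).
#' @return Character vector of labels.
#' @export
motif_hierarchy <- function(fixed_list) {
  n <- length(fixed_list)
  key <- vapply(fixed_list, function(f)
    paste(sort(paste(names(f), f, sep = ":")), collapse = ","), character(1))
  if (anyDuplicated(key)) stop("duplicate motifs in hierarchy input")
  subset_of <- function(a, b) {  # a strict subset of b
    if (length(a) >= length(b)) return(FALSE)
    all(names(a) %in% names(b)) && all(b[names(a)] == a)
  }
  has_parent <- vapply(seq_len(n), function(i)
    any(vapply(seq_len(n), function(j)
      j != i && subset_of(fixed_list[[j]], fixed_list[[i]]), logical(1))),
    logical(1))
  has_child <- vapply(seq_len(n), function(i)
    any(vapply(seq_len(n), function(j)
      j != i && subset_of(fixed_list[[i]], fixed_list[[j]]), logical(1))),
    logical(1))
  ifelse(has_parent, "child", ifelse(has_child, "parent", "orphan"))
}

#' Minimum foreground matches under the 0.5% retention rule
#'
#' Motifs must appear in at least `fraction` of the set's sites to be
#' retained; the count is rounded half-up to the nearest integer with a
#' floor of 1.
#'
#' @param n_sites Number of sites in the set.
#' @param fraction Retention fraction (default 0.005).
#' @return Integer threshold.
#' @export
retention_threshold <- function(n_sites, fraction = 0.005) {
  stopifnot(n_sites >= 1)
  max(1L, as.integer(floor(n_sites * fraction + 0.5)))
}

#' Hydrophobic residues of the SUMO consensus
#'
#' The large hydrophobic class used when matching the canonical
#' psi-K-x-E/D and inverted E/D-x-K-psi consensus motifs.
#'
#' @return Character vector.
#' @export
scm_hydrophobic <- function() c("I", "V", "L", "F", "M", "A", "W", "P")

#' Write motif results to TSV
#'
#' @param motifs data.frame from [motifx()].
#' @param path Output path.
#' @export
write_motif_tsv <- function(motifs, path) {
  out <- motifs[, c("pattern", "fg_matches", "fg_total", "bg_matches",
                    "bg_total", "fold_enrichment", "max_step_p")]
  out$class <- vapply(motifs$fixed, classify_motif, character(1))
  if (nrow(out) > 1) out$hierarchy <- motif_hierarchy(motifs$fixed)
  else out$hierarchy <- rep("orphan", nrow(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
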