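# Independent oracles used to freeze expected values. These deliberately
# take different routes than the package code.

# Residue masses from elemental composition (atomic monoisotopic masses),
# independent of the package's 5-decimal residue table.
elemental_residue_mass <- local({
  H <- 1.0078250319; C <- 12; N <- 14.0030740052
  O <- 15.9949146221; S <- 31.97207069
  f <- function(c, h, n, o, s = 0) c * C + h * H + n * N + o * O + s * S
  c(G = f(2, 3, 1, 1), A = f(3, 5, 1, 1), S = f(3, 5, 1, 2),
    P = f(5, 7, 1, 1), V = f(5, 9, 1, 1), T = f(4, 7, 1, 2),
    C = f(3, 5, 1, 1, 1), L = f(6, 11, 1, 1), I = f(6, 11, 1, 1),
    N = f(4, 6, 2, 2), D = f(4, 5, 1, 3), Q = f(5, 8, 2, 2),
    K = f(6, 12, 2, 1), E = f(5, 7, 1, 3), M = f(5, 9, 1, 1, 1),
    H = f(6, 7, 3, 1), F = f(9, 9, 1, 1), R = f(6, 12, 4, 1),
    Y = f(9, 9, 1, 2), W = f(11, 10, 2, 1))
})
ORACLE_WATER <- 2 * 1.0078250319 + 15.9949146221
ORACLE_PROTON <- 1.00727646688

# Brute-force digestion oracle: enumerate all substrings and keep those
# whose boundaries are termini or cleavage points and whose internal
# cleavage-point count is within the missed-cleavage budget.
oracle_digest <- function(sequence, rule, max_missed, met_removal = FALSE) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cuts <- switch(rule,
    lysC = {
      i <- which(res == "K"); i <- i[i < n]
      i[res[i + 1L] != "P"]
    },
    aspN_before_DE = {
      i <- which(res %in% c("D", "E")); (i - 1L)[i > 1L]
    },
    gluC_after_DE = {
      i <- which(res %in% c("D", "E")); i[i < n]
    },
    trypsin = {
      i <- which(res %in% c("K", "R")); i <- i[i < n]
      i[res[i + 1L] != "P"]
    })
  boundaries <- c(0L, cuts, n)
  out <- list()
  for (a in seq_len(n)) for (b in a:n) {
    if (!((a - 1L) %in% boundaries) || !(b %in% boundaries)) next
    internal <- sum(cuts > (a - 1L) & cuts < b)
    if (internal > max_missed) next
    out[[length(out) + 1L]] <- data.frame(
      start = a, sequence = substring(sequence, a, b),
      missed_cleavages = internal, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (met_removal && res[1] == "M") {
    nt <- out[out$start == 1L & nchar(out$sequence) > 1L, , drop = FALSE]
    if (nrow(nt)) {
      nt$sequence <- substring(nt$sequence, 2L)
      nt$start <- 2L
      out <- rbind(out, nt)
    }
  }
  out[order(out$start, nchar(out$sequence), out$sequence), , drop = FALSE]
}

peptide_key <- function(df)
  sort(paste(df$start, df$sequence, df$missed_cleavages, sep = "|"))

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mann_whitney <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  ustat <- function(idx) {
    xs <- all[idx]; ys <- all[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- ustat(seq_len(n1))
  combos <- utils::combn(length(all), n1)
  us <- apply(combos, 2, ustat)
  mu <- n1 * (length(all) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Stepwise exhaustive motif-x oracle: plain loops, binomial tail via
# summed dbinom, spec tie-break order.
oracle_motifx <- function(fg, bg, min_occ, p_max, residues) {
  width <- nchar(fg[1]); center <- (width + 1L) %/% 2L
  fg_m <- do.call(rbind, strsplit(fg, ""))
  bg_full <- do.call(rbind, strsplit(bg, ""))
  motifs <- list()
  repeat {
    bg_m <- bg_full
    fixed_col <- integer(0); fixed_res <- character(0)
    cur_fg <- fg_m
    repeat {
      best <- NULL
      for (col in setdiff(seq_len(width), c(center, fixed_col))) {
        bg_col <- bg_m[, col]; bg_col <- bg_col[bg_col != "X"]
        if (!length(bg_col)) next
        for (res in residues) {
          k <- sum(cur_fg[, col] == res)
          if (k < min_occ) next
          p <- sum(bg_col == res) / length(bg_col)
          pv <- sum(stats::dbinom(k:nrow(cur_fg), nrow(cur_fg), p))
          if (pv > p_max) next
          cand <- list(col = col, res = res, k = k, pv = pv, ao = abs(col - center))
          better <- is.null(best) || pv < best$pv ||
            (pv == best$pv && (k > best$k ||
              (k == best$k && (cand$ao < best$ao ||
                (cand$ao == best$ao && res < best$res)))))
          if (better) best <- cand
        }
      }
      if (is.null(best)) break
      fixed_col <- c(fixed_col, best$col); fixed_res <- c(fixed_res, best$res)
      cur_fg <- cur_fg[cur_fg[, best$col] == best$res, , drop = FALSE]
      bg_m <- bg_m[bg_m[, best$col] == best$res, , drop = FALSE]
    }
    if (!length(fixed_col)) break
    pattern <- rep(".", width); pattern[center] <- "K"
    pattern[fixed_col] <- fixed_res
    motifs[[length(motifs) + 1L]] <- paste(pattern, collapse = "")
    match_rows <- rep(TRUE, nrow(fg_m))
    for (i in seq_along(fixed_col))
      match_rows <- match_rows & fg_m[, fixed_col[i]] == fixed_res[i]
    fg_m <- fg_m[!match_rows, , drop = FALSE]
    if (nrow(fg_m) < min_occ) break
  }
  unlist(motifs)
}

# Brute-force tier re-derivation from a per-dataset FLR map.
oracle_tier <- function(flrs, sub1 = 0.01, keep_max = 0.05) {
  n1 <- sum(flrs < sub1)
  if (n1 >= 2) return("Gold")
  if (n1 == 1) return("Silver")
  if (min(flrs) < keep_max) return("Bronze")
  NA_character_
}

# Small random site table for build tests.
random_flr_map <- function(n_datasets) {
  stats::runif(sample(n_datasets, 1L), 0, 0.08)
}
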