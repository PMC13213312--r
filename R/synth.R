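# Synthetic proteomes, planted SUMO sites, PSM tables, spectra and
# annotation tracks. The generator's job is to realize the statistical
# structure the analyses assume - proteome-like residue frequencies,
# motif adherence, disorder bias, a controlled mislocalization rate with
# decoy-alanine hits, diagnostic remnant ions - so every stage of the
# pipeline is testable without downloads. Defaults mirror the quantities
# the analyses report (29% core-motif adherence, disorder odds 2.4,
# 32.2% background disorder).

#' Human-proteome-like amino-acid frequencies
#'
#' Approximate residue frequencies of the human reference proteome;
#' lysine (5.7%) and alanine (7.0%) are deliberately close, the situation
#' the decoy-alanine FLR method relies on.
#'
#' @return Named numeric vector summing to 1.
#' @export
human_aa_frequencies <- function() {
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
         P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)
  f / sum(f)
}

#' Simulation configuration
#'
#' @param seed Integer master seed; every generator derives its stream
#'   from it, so a run is fully reproducible.
#' @param n_proteins Number of synthetic proteins.
#' @param mean_length Mean protein length (log-normal lengths).
#' @param aa_freq Named residue frequency vector.
#' @param n_sites Number of planted SUMO sites.
#' @param motif_mix Named fractions of planted sites per motif class
#'   (`kxe`, `exk`, `kxd`, `dxk`; remainder unconstrained). Defaults are
#'   the Gold-set adherence rates.
#' @param disorder_background Proteome disorder proportion (0.322).
#' @param disorder_odds Odds ratio of planted sites for disorder (2.4).
#' @param epsilon Mislocalization rate: each PSM reports a wrong lysine
#'   with probability `epsilon` and the decoy alanine with probability
#'   `epsilon` (the decoy method's core assumption that false
#'   localizations hit A and wrong K equally often, matching their
#'   near-equal proteome frequencies).
#' @param obs_prob Probability a planted site is observed in a given
#'   pseudo-dataset.
#' @param n_datasets Number of pseudo-dataset blocks (exercises tiering).
#' @param redundancy_mean Mean PSMs per observed site (shifted Poisson).
#' @param decoy_psm_fraction Decoy-protein PSMs injected, as a fraction
#'   of target PSMs.
#' @param prob_correct_shape,prob_wrong_shape Beta parameters for
#'   localization probabilities of correct / incorrect assignments.
#' @param diag_fraction Fraction of MS2 spectra carrying remnant ions.
#' @param diag_rel_intensity Remnant peak intensity relative to base.
#' @param n_noise_peaks Uniform noise peaks per spectrum.
#' @param phospho_rate Background phosphosite rate on S/T/Y.
#' @param phospho_excess Additional rate at -2/+1/+5 of planted sites.
#' @param variant_rate Per-residue variant rate.
#' @param disease_background,disease_at_site Disease-associated variant
#'   proportions away from / at planted lysines and their -2 position.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 120L, mean_length = 400L,
                       aa_freq = human_aa_frequencies(),
                       n_sites = 600L,
                       motif_mix = c(kxe = 0.29, exk = 0.127,
                                     kxd = 0.063, dxk = 0.103),
                       disorder_background = 0.322, disorder_odds = 2.4,
                       epsilon = 0.05, obs_prob = 0.6, n_datasets = 3L,
                       redundancy_mean = 2, decoy_psm_fraction = 0.10,
                       prob_correct_shape = c(12, 1.5),
                       prob_wrong_shape = c(2, 4),
                       diag_fraction = 0.65, diag_rel_intensity = 0.5,
                       n_noise_peaks = 30L,
                       phospho_rate = 0.04, phospho_excess = 0.25,
                       variant_rate = 0.02,
                       disease_background = 0.057, disease_at_site = 0.066) {
  stopifnot(sum(motif_mix) <= 1, all(motif_mix >= 0),
            epsilon >= 0, epsilon <= 0.5,
            abs(sum(aa_freq) - 1) < 1e-6, all(aa_freq >= 0))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic proteome
#'
#' Log-normal lengths, i.i.d. residues at the configured frequencies,
#' every protein starting with methionine.
#'
#' @param config A [sim_config()].
#' @return data.frame of protein records.
#' @export
gen_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_proteins < 1L) stop("n_proteins must be positive")
  if (any(config$aa_freq < 0) || sum(config$aa_freq) <= 0)
    stop("degenerate residue frequency vector")
  .with_seed(config$seed + 101L, {
    lens <- pmax(60L, round(stats::rlnorm(config$n_proteins,
                                          log(config$mean_length), 0.4)))
    seqs <- vapply(lens, function(n) {
      paste(c("M", sample(names(config$aa_freq), n - 1L, replace = TRUE,
                          prob = config$aa_freq)), collapse = "")
    }, character(1))
    protein_record(sprintf("SYNP%04d", seq_len(config$n_proteins)), seqs)
  })
}

#' Plant SUMO sites with motif adherence and disorder bias
#'
#' Samples lysines (min spacing 5 residues), edits the +2 / -2 flank to
#' realize the configured motif-class mixture, and generates a
#' per-residue disorder track in which planted sites are disordered with
#' the probability implied by the configured odds ratio over the
#' background (odds 2.4 over 32.2% gives ~53% disordered sites).
#'
#' @param proteome data.frame from [gen_proteome()].
#' @param config A [sim_config()].
#' @return List: `proteome` (flank-edited), `sites` (accession, position,
#'   motif_class), `disorder` (accession, position, score; one row per
#'   residue).
#' @export
plant_sites <- function(proteome, config) {
  .with_seed(config$seed + 202L, {
    # candidate lysines, >= 3 from the N-terminus, >= 2 from the C-terminus
    cand <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(r) {
      s <- proteome$sequence[r]
      pos <- which(strsplit(s, "")[[1]] == "K")
      pos <- pos[pos >= 3L & pos <= nchar(s) - 2L]
      if (!length(pos)) return(NULL)
      data.frame(row = r, position = pos)
    }))
    if (is.null(cand) || nrow(cand) < config$n_sites)
      stop("insufficient lysines to plant ", config$n_sites, " sites")
    cand <- cand[sample(nrow(cand)), ]
    # greedy min-spacing selection
    sel <- integer(0)
    taken <- list()
    for (i in seq_len(nrow(cand))) {
      r <- cand$row[i]; p <- cand$position[i]
      prev <- taken[[as.character(r)]]
      if (!is.null(prev) && any(abs(prev - p) < 5L)) next
      sel <- c(sel, i)
      taken[[as.character(r)]] <- c(prev, p)
      if (length(sel) == config$n_sites) break
    }
    if (length(sel) < config$n_sites)
      stop("insufficient spaced lysines to plant ", config$n_sites, " sites")
    sites <- cand[sel, ]
    classes <- c(names(config$motif_mix), "none")
    probs <- c(config$motif_mix, 1 - sum(config$motif_mix))
    sites$motif_class <- sample(classes, nrow(sites), replace = TRUE, prob = probs)
    # flank edits realizing the class
    seqs <- proteome$sequence
    for (i in seq_len(nrow(sites))) {
      r <- sites$row[i]; p <- sites$position[i]
      edit <- switch(sites$motif_class[i],
                     kxe = c(2L, "E"), exk = c(-2L, "E"),
                     kxd = c(2L, "D"), dxk = c(-2L, "D"), NULL)
      if (!is.null(edit)) {
        at <- p + as.integer(edit[1])
        substr(seqs[r], at, at) <- edit[2]
      }
    }
    proteome$sequence <- seqs
    sites$accession <- proteome$accession[sites$row]
    # disorder track: planted-site residues biased by the configured odds
    r0 <- config$disorder_background / (1 - config$disorder_background)
    p_site <- config$disorder_odds * r0 / (1 + config$disorder_odds * r0)
    disorder <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(r) {
      n <- nchar(proteome$sequence[r])
      dis <- stats::runif(n) < config$disorder_background
      data.frame(accession = proteome$accession[r], position = seq_len(n),
                 disordered = dis, stringsAsFactors = FALSE)
    }))
    skey <- paste(sites$accession, sites$position, sep = "\r")
    dkey <- paste(disorder$accession, disorder$position, sep = "\r")
    idx <- match(skey, dkey)
    disorder$disordered[idx] <- stats::runif(length(idx)) < p_site
    disorder$score <- ifelse(disorder$disordered,
                             stats::runif(nrow(disorder), 0.5 + 1e-6, 1),
                             stats::runif(nrow(disorder), 0, 0.5))
    disorder$disordered <- NULL
    rownames(sites) <- NULL
    list(proteome = proteome,
         sites = sites[, c("accession", "position", "motif_class")],
         disorder = disorder)
  })
}

#' Generate a PSM table with a controlled mislocalization rate
#'
#' Each planted site is observed in each pseudo-dataset with probability
#' `obs_prob`; each observation yields a shifted-Poisson number of PSMs.
#' A PSM reports the correct lysine with probability `1 - 2 epsilon`, a
#' wrong lysine in the peptide with probability `epsilon`, and a decoy
#' alanine with probability `epsilon` (falling back to whichever
#' candidate class exists). Correct assignments draw localization
#' probabilities from a high-concentration Beta, incorrect ones from a
#' low one. Decoy-protein PSMs with lower scores are injected for FDR
#' testing.
#'
#' @param planted List from [plant_sites()].
#' @param config A [sim_config()].
#' @param footprint_mass Modification mass written into `mod_string`.
#' @return List: `psms` (the PSM table), `truth` (per target PSM: the
#'   planted site, the assigned site and whether it is correct).
#' @export
gen_psm_table <- function(planted, config, footprint_mass = 471.21) {
  .with_seed(config$seed + 303L, {
    proteome <- planted$proteome
    seqs <- stats::setNames(proteome$sequence, proteome$accession)
    sites <- planted$sites
    planted_key <- paste(sites$accession, sites$position)
    psms <- list(); truth <- list()
    id <- 0L
    for (i in seq_len(nrow(sites))) {
      acc <- sites$accession[i]; pos <- sites$position[i]
      s <- seqs[[acc]]
      start <- max(1L, pos - 10L)
      end <- min(nchar(s), pos + 10L)
      pep <- substring(s, start, end)
      res <- strsplit(pep, "")[[1]]
      site_in_pep <- pos - start + 1L
      # wrong-K candidates exclude genuinely SUMOylated lysines: a false
      # localization onto a real site is invisible to the decoy method and
      # is not part of the planted error model
      alt_k <- setdiff(which(res == "K"), site_in_pep)
      if (length(alt_k))
        alt_k <- alt_k[!(paste(acc, start + alt_k - 1L) %in% planted_key)]
      alas <- which(res == "A")
      misloc_possible <- length(alt_k) > 0L && length(alas) > 0L
      for (ds in seq_len(config$n_datasets)) {
        if (stats::runif(1) > config$obs_prob) next
        n_psm <- 1L + stats::rpois(1, max(config$redundancy_mean - 1, 0))
        for (k in seq_len(n_psm)) {
          id <- id + 1L
          u <- stats::runif(1)
          assigned <- site_in_pep; kind <- "correct"
          # mislocalize only when both candidate classes exist, keeping the
          # decoy and wrong-K rates exactly balanced
          if (misloc_possible && u < config$epsilon) {
            assigned <- if (length(alas) == 1L) alas else sample(alas, 1L)
            kind <- "decoy"
          } else if (misloc_possible && u < 2 * config$epsilon) {
            assigned <- if (length(alt_k) == 1L) alt_k else sample(alt_k, 1L)
            kind <- "wrongK"
          }
          shp <- if (kind == "correct") config$prob_correct_shape else config$prob_wrong_shape
          prob <- stats::rbeta(1, shp[1], shp[2])
          psms[[id]] <- data.frame(
            spectrum_ref = sprintf("scan%06d", id),
            dataset_id = sprintf("SYNPXD%02d", ds),
            peptide = pep, protein_refs = acc,
            peptide_starts = as.character(start),
            search_score = stats::rnorm(1, 4, 1),
            is_decoy_protein = FALSE,
            mod_string = sprintf("%d:%.2f", assigned, footprint_mass),
            site_prob_string = sprintf("%d:%s:%.6f", assigned, res[assigned], prob),
            stringsAsFactors = FALSE)
          truth[[id]] <- data.frame(
            spectrum_ref = sprintf("scan%06d", id),
            dataset_id = sprintf("SYNPXD%02d", ds),
            accession = acc, true_position = pos,
            assigned_position = start + assigned - 1L,
            assigned_residue = res[assigned],
            correct = kind == "correct", kind = kind,
            stringsAsFactors = FALSE)
        }
      }
    }
    psms <- do.call(rbind, psms)
    truth <- do.call(rbind, truth)
    # decoy-protein PSMs for FDR control
    n_dec <- round(config$decoy_psm_fraction * nrow(psms))
    if (n_dec > 0) {
      rev1 <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
      pick <- sample(nrow(psms), n_dec, replace = TRUE)
      dec <- psms[pick, ]
      dec$spectrum_ref <- sprintf("decoyscan%06d", seq_len(n_dec))
      dec$peptide <- vapply(dec$peptide, rev1, character(1), USE.NAMES = FALSE)
      dec$protein_refs <- paste0("DECOY_", dec$protein_refs)
      dec$is_decoy_protein <- TRUE
      dec$search_score <- stats::rnorm(n_dec, 1.0, 1)
      dec$mod_string <- ""
      dec$site_prob_string <- ""
      psms <- rbind(psms, dec)
    }
    rownames(psms) <- NULL
    list(psms = psms, truth = truth)
  })
}

#' Generate MS2 spectra carrying remnant diagnostic ions
#'
#' A configured fraction of spectra receive the footprint's b/y/a ions
#' and intact ion at `diag_rel_intensity` of the base peak, on top of a
#' base peak (intensity 1000) and uniform noise peaks.
#'
#' @param config A [sim_config()].
#' @param n_spectra Number of MS2 spectra.
#' @param footprint Remnant sequence for the diagnostic ions.
#' @param pyro Pyroglutamate flag for the remnant.
#' @return List: `spectra` (list of `spectrum` records), `planted`
#'   (logical vector marking spectra given diagnostic peaks).
#' @export
gen_spectra <- function(config, n_spectra = 200L, footprint = "QQTGG",
                        pyro = FALSE) {
  .with_seed(config$seed + 404L, {
    ions <- remnant_diagnostic_ions(footprint, pyro = pyro)
    planted <- stats::runif(n_spectra) < config$diag_fraction
    spectra <- lapply(seq_len(n_spectra), function(i) {
      mz <- stats::runif(config$n_noise_peaks, 150, 1500)
      inten <- stats::runif(config$n_noise_peaks, 1, 300)
      mz <- c(mz, stats::runif(1, 400, 1200))  # base peak
      inten <- c(inten, 1000)
      if (planted[i]) {
        mz <- c(mz, ions)
        inten <- c(inten, rep(config$diag_rel_intensity * 1000, length(ions)))
      }
      spectrum_record(sprintf("synscan%05d", i), 2L, mz, inten,
                      precursor_mz = stats::runif(1, 400, 1200))
    })
    list(spectra = spectra, planted = planted)
  })
}

#' Generate annotation tracks consistent with the planted world
#'
#' Produces rASA values (disordered residues systematically more
#' exposed), secondary-structure spans confined to ordered regions,
#' amino-acid variants with elevated disease proportions at planted
#' lysines and their -2 position, and phosphosites with positional excess
#' at -2, +1 and +5 of planted sites.
#'
#' @param planted List from [plant_sites()].
#' @param config A [sim_config()].
#' @return List of data.frames: `rasa`, `spans`, `variants`,
#'   `phosphosites`.
#' @export
gen_annotations <- function(planted, config) {
  .with_seed(config$seed + 505L, {
    proteome <- planted$proteome
    disorder <- planted$disorder
    sites <- planted$sites
    # rASA for every lysine: exposure tracks disorder
    dis_key <- paste(disorder$accession, disorder$position, sep = "\r")
    lys <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(r) {
      pos <- which(strsplit(proteome$sequence[r], "")[[1]] == "K")
      if (!length(pos)) return(NULL)
      data.frame(accession = proteome$accession[r], position = pos,
                 stringsAsFactors = FALSE)
    }))
    idx <- match(paste(lys$accession, lys$position, sep = "\r"), dis_key)
    is_dis <- disorder$score[idx] > 0.5
    lys$rasa <- ifelse(is_dis, stats::rbeta(nrow(lys), 5, 3),
                       stats::rbeta(nrow(lys), 3, 5))
    # structure spans: runs of ordered residues get an element
    spans <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(r) {
      acc <- proteome$accession[r]
      sc <- disorder$score[disorder$accession == acc]
      ordered <- sc <= 0.5
      rl <- rle(ordered)
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
      keep <- rl$values & rl$lengths >= 6L
      if (!any(keep)) return(NULL)
      data.frame(accession = acc, start = starts[keep], end = ends[keep],
                 element = sample(c("helix", "strand", "turn", "coiled_coil"),
                                  sum(keep), replace = TRUE,
                                  prob = c(0.45, 0.25, 0.2, 0.1)),
                 stringsAsFactors = FALSE)
    }))
    # variants: uniform positions, elevated disease proportion at planted
    # lysines and their -2 position
    total_len <- sum(nchar(proteome$sequence))
    n_var <- stats::rpois(1, config$variant_rate * total_len)
    prot_idx <- sample(nrow(proteome), n_var, replace = TRUE,
                       prob = nchar(proteome$sequence))
    vpos <- vapply(prot_idx, function(r)
      sample.int(nchar(proteome$sequence[r]), 1L), integer(1))
    variants <- data.frame(accession = proteome$accession[prot_idx],
                           position = vpos, stringsAsFactors = FALSE)
    hot <- c(paste(sites$accession, sites$position, sep = "\r"),
             paste(sites$accession, sites$position - 2L, sep = "\r"))
    at_hot <- paste(variants$accession, variants$position, sep = "\r") %in% hot
    variants$disease_associated <- stats::runif(n_var) <
      ifelse(at_hot, config$disease_at_site, config$disease_background)
    variants$ref_aa <- substring(seqs_at(proteome, variants), 1L, 1L)
    variants$alt_aa <- sample(names(config$aa_freq), n_var, replace = TRUE)
    variants$synonymous <- variants$ref_aa == variants$alt_aa
    # phosphosites: background on S/T/Y plus excess at -2/+1/+5
    sty <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(r) {
      pos <- which(strsplit(proteome$sequence[r], "")[[1]] %in% c("S", "T", "Y"))
      if (!length(pos)) return(NULL)
      data.frame(accession = proteome$accession[r], position = pos,
                 stringsAsFactors = FALSE)
    }))
    near <- c(paste(sites$accession, sites$position - 2L, sep = "\r"),
              paste(sites$accession, sites$position + 1L, sep = "\r"),
              paste(sites$accession, sites$position + 5L, sep = "\r"))
    at_near <- paste(sty$accession, sty$position, sep = "\r") %in% near
    rate <- ifelse(at_near, config$phospho_rate + config$phospho_excess,
                   config$phospho_rate)
    phos <- sty[stats::runif(nrow(sty)) < rate, , drop = FALSE]
    rownames(phos) <- NULL
    list(rasa = lys, spans = spans, variants = variants, phosphosites = phos)
  })
}

# residue at each (accession, position) row of df
seqs_at <- function(proteome, df) {
  seqs <- stats::setNames(proteome$sequence, proteome$accession)
  vapply(seq_len(nrow(df)), function(r)
    substring(seqs[[df$accession[r]]], df$position[r], df$position[r]),
    character(1))
}

#' End-to-end synthetic dataset
#'
#' Convenience wrapper running the full generator chain.
#'
#' @param config A [sim_config()].
#' @return List: `proteome`, `sites`, `disorder`, `psms`, `truth`,
#'   `annotations`.
#' @export
gen_dataset <- function(config) {
  proteome <- gen_proteome(config)
  planted <- plant_sites(proteome, config)
  psm <- gen_psm_table(planted, config)
  ann <- gen_annotations(planted, config)
  list(proteome = planted$proteome, sites = planted$sites,
       disorder = planted$disorder, psms = psm$psms, truth = psm$truth,
       annotations = ann)
}
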