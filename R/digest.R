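# In-silico protease digestion for peptide search databases. Multi-enzyme
# protocols (Lys-C then Asp-N or Glu-C) with up to eight missed cleavages
# exceed common search-engine limits, so peptides are enumerated here and
# written as a peptide FASTA.

#' Construct a protein record
#'
#' @param accession Identifier.
#' @param sequence Uppercase residue string (X/U/B/Z tolerated on read).
#' @param is_decoy,is_contaminant Flags.
#' @return A one-row data.frame.
#' @export
protein_record <- function(accession, sequence, is_decoy = FALSE,
                           is_contaminant = FALSE) {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) == 0L)) stop("empty protein sequence")
  data.frame(accession = accession, sequence = sequence,
             is_decoy = is_decoy, is_contaminant = is_contaminant,
             stringsAsFactors = FALSE)
}

# Cleavage rules return the 0-based cut offsets inside a sequence: a cut at
# offset i splits s into s[1..i] and s[i+1..n]. Offsets exclude 0 and n.
.cut_offsets <- function(sequence, rule) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  pos <- switch(rule,
    lysC = {  # after K unless followed by P
      i <- which(res[-n] == "K")
      i[res[i + 1L] != "P"]
    },
    aspN_before_DE = which(res[-1L] %in% c("D", "E")),  # before D/E
    gluC_after_DE = {  # after D or E
      i <- which(res[-n] %in% c("D", "E"))
      i
    },
    trypsin = {  # after K/R unless followed by P (synthetic pipeline only)
      i <- which(res[-n] %in% c("K", "R"))
      i[res[i + 1L] != "P"]
    },
    stop("unknown cleavage rule: ", rule))
  as.integer(pos)
}

# Enumerate peptides between cut points with 0..max_missed internal missed
# cleavages. Returns data.frame(start, sequence, missed_cleavages) with
# start 1-based within `sequence`.
.enumerate_peptides <- function(sequence, rule, max_missed) {
  cuts <- c(0L, .cut_offsets(sequence, rule), nchar(sequence))
  nfrag <- length(cuts) - 1L
  out <- vector("list", 0L)
  k <- 0L
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      k <- k + 1L
      out[[k]] <- c(cuts[i] + 1L, cuts[j + 1L], j - i)
    }
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1],
             sequence = substring(sequence, m[, 1], m[, 2]),
             missed_cleavages = m[, 3], stringsAsFactors = FALSE)
}

#' Lys-C in-silico digestion of a protein
#'
#' Cleaves after lysine unless the next residue is proline, allowing up to
#' `max_missed` missed cleavages. When `met_removal` is set and the protein
#' starts with methionine, each N-terminal peptide is additionally emitted
#' without the leading M (leader-methionine processing). A protein with no
#' Lys-C site yields its whole sequence (plus the Met-removed variant).
#'
#' @param protein One-row data.frame from [protein_record()] (or any row
#'   with `accession` and `sequence`).
#' @param max_missed Maximum missed cleavages (default 8).
#' @param met_removal Emit leader-Met-removed N-terminal variants.
#' @return data.frame with columns `sequence`, `parent_accession`, `start`
#'   (1-based in parent), `missed_cleavages`, `stage`.
#' @export
lysC_digest <- function(protein, max_missed = 8L, met_removal = TRUE) {
  digest_protein(protein, rule = "lysC", max_missed = max_missed,
                 met_removal = met_removal, stage = "lysC")
}

#' Digest a protein under a named cleavage rule
#'
#' Generic engine behind [lysC_digest()]; `rule` is one of `"lysC"`,
#' `"aspN_before_DE"`, `"gluC_after_DE"`, `"trypsin"`.
#'
#' @inheritParams lysC_digest
#' @param rule Cleavage rule name.
#' @param stage Provenance label stored on every peptide.
#' @return data.frame as in [lysC_digest()].
#' @export
digest_protein <- function(protein, rule, max_missed = 8L,
                           met_removal = TRUE, stage = rule) {
  seqs <- protein$sequence
  if (is.null(seqs) || any(!nzchar(seqs))) stop("empty protein sequence")
  out <- lapply(seq_len(nrow(protein)), function(r) {
    s <- protein$sequence[r]
    pep <- .enumerate_peptides(s, rule, max_missed)
    pep$parent_accession <- protein$accession[r]
    pep$stage <- stage
    if (met_removal && startsWith(s, "M")) {
      nt <- pep[pep$start == 1L & nchar(pep$sequence) > 1L, , drop = FALSE]
      if (nrow(nt)) {
        nt$sequence <- substring(nt$sequence, 2L)
        nt$start <- 2L
        nt$stage <- paste0(stage, "_met_removed")
        pep <- rbind(pep, nt)
      }
    }
    pep
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("sequence", "parent_accession", "start", "missed_cleavages", "stage")]
}

#' Secondary digestion of first-stage peptides
#'
#' Re-digests each peptide under an Asp-N-like (cut before D/E) or
#' Glu-C-like (cut after D/E) rule with its own missed-cleavage budget,
#' counted within the stage. Duplicates on (sequence, parent, start) are
#' collapsed.
#'
#' @param peptides data.frame from [lysC_digest()].
#' @param mode `"aspN_before_DE"` or `"gluC_after_DE"`.
#' @param max_missed Missed cleavages within this stage (default 8).
#' @return data.frame with the same columns, `start` in protein
#'   coordinates, `stage` updated.
#' @export
secondary_digest <- function(peptides, mode = c("aspN_before_DE", "gluC_after_DE"),
                             max_missed = 8L) {
  mode <- match.arg(mode)
  stage_label <- if (mode == "aspN_before_DE") "lysC_aspN" else "lysC_gluC"
  out <- lapply(seq_len(nrow(peptides)), function(r) {
    sub <- .enumerate_peptides(peptides$sequence[r], mode, max_missed)
    data.frame(sequence = sub$sequence,
               parent_accession = peptides$parent_accession[r],
               start = peptides$start[r] + sub$start - 1L,
               missed_cleavages = sub$missed_cleavages,
               stage = stage_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[!duplicated(out[, c("sequence", "parent_accession", "start")]), ]
  rownames(out) <- NULL
  out
}

#' Reversed-sequence decoy proteins
#'
#' Plumbing stand-in for a full decoy generator: one decoy per target with
#' the sequence reversed and the accession prefixed.
#'
#' @param proteins data.frame of target proteins.
#' @param prefix Accession prefix for decoys.
#' @return data.frame of decoy [protein_record()] rows.
#' @export
reversal_decoys <- function(proteins, prefix = "DECOY_") {
  stopifnot(!any(proteins$is_decoy))
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  protein_record(paste0(prefix, proteins$accession),
                 vapply(proteins$sequence, rev1, character(1), USE.NAMES = FALSE),
                 is_decoy = TRUE, is_contaminant = proteins$is_contaminant)
}

# ---- FASTA I/O --------------------------------------------------------------

#' Read a proteome FASTA
#'
#' @param path FASTA path. Decoy and contaminant status are inferred from
#'   accession prefixes.
#' @param decoy_prefix,contaminant_prefix Accession prefixes.
#' @return data.frame of [protein_record()] rows.
#' @export
read_protein_fasta <- function(path, decoy_prefix = "DECOY_",
                               contaminant_prefix = "CONTAM_") {
  aa <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aa))
  protein_record(acc, as.character(aa),
                 is_decoy = startsWith(acc, decoy_prefix),
                 is_contaminant = startsWith(acc, contaminant_prefix))
}

#' Write a proteome FASTA
#'
#' @param proteins data.frame of protein records.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$accession
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write a peptide FASTA with provenance headers
#'
#' Headers encode parent accession, 1-based start, missed cleavages and
#' stage as `>parent|start|mc|stage`, so distinct records with identical
#' sequences remain distinct and the file round-trips losslessly through
#' [read_peptide_fasta()].
#'
#' @param peptides data.frame from the digestion operations.
#' @param path Output path.
#' @export
write_peptide_fasta <- function(peptides, path) {
  if (is.null(peptides) || nrow(peptides) == 0L) stop("no peptides to write")
  hdr <- paste(peptides$parent_accession, peptides$start,
               peptides$missed_cleavages, peptides$stage, sep = "|")
  aa <- Biostrings::AAStringSet(peptides$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a peptide FASTA written by [write_peptide_fasta()]
#'
#' @param path FASTA path.
#' @return data.frame with the digestion columns.
#' @export
read_peptide_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  data.frame(sequence = as.character(aa),
             parent_accession = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             missed_cleavages = as.integer(vapply(parts, `[`, "", 3L)),
             stage = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE, row.names = NULL)
}
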