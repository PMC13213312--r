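# Monoisotopic mass arithmetic for SUMO remnant footprints and their
# fragment ions. All masses in Daltons.

#' Monoisotopic residue masses and mass constants
#'
#' Standard monoisotopic residue (amino-acid minus water) masses for the 20
#' standard amino acids, to five decimal places, plus the constants needed
#' for fragment-ion arithmetic.
#'
#' @param extra Optional named numeric vector of residue masses that
#'   override or extend the built-in table (e.g. read from a two-column
#'   TSV with [read_mass_table()]).
#' @return An object of class `aa_mass_table`: a list with elements
#'   `residue_mass` (named numeric vector), `water`, `proton`, `ammonia`
#'   and `carbon_monoxide`.
#' @examples
#' tbl <- aa_mass_table()
#' tbl$residue_mass[["G"]]  # 57.02146
#' @export
aa_mass_table <- function(extra = NULL) {
  residue_mass <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
  if (!is.null(extra)) {
    stopifnot(is.numeric(extra), !is.null(names(extra)), all(extra > 0))
    residue_mass[names(extra)] <- extra
  }
  structure(list(
    residue_mass = residue_mass,
    water = 18.010565,
    proton = 1.007276,
    ammonia = 17.026549,
    carbon_monoxide = 27.994915), class = "aa_mass_table")
}

#' Read a residue mass table from TSV
#'
#' Two columns, `residue` and `mass`, no header required if the first row
#' parses as a mass. Values override the built-in table.
#'
#' @param path Path to a tab-separated file.
#' @return An `aa_mass_table` with overrides applied.
#' @export
read_mass_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("residue", "mass"),
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(df$residue[1]), "residue")) df <- df[-1, , drop = FALSE]
  m <- as.numeric(df$mass)
  names(m) <- df$residue
  aa_mass_table(extra = m)
}

.residue_masses <- function(sequence, table) {
  if (nchar(sequence) == 0L) return(numeric(0))
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(table$residue_mass))
  if (length(unknown))
    stop("unknown residue symbol(s): ", paste(unique(unknown), collapse = ", "))
  unname(table$residue_mass[res])
}

#' Mass added to a lysine by a SUMO remnant footprint
#'
#' The remnant tail is attached through an isopeptide bond, so no water is
#' added: the delta mass is the plain sum of residue masses. When the
#' N-terminal glutamine of the tail has cyclized to pyroglutamate (`pyro`),
#' one ammonia is lost.
#'
#' @param sequence Residue string of the remnant tail (e.g. `"QQTGG"`);
#'   the empty string gives 0.
#' @param pyro Logical; subtract one ammonia for N-terminal pyroglutamate.
#' @param table An [aa_mass_table()].
#' @return Delta mass in Da.
#' @examples
#' remnant_delta_mass("QQTGG")            # 471.20776
#' remnant_delta_mass("QQTGG", pyro = TRUE)  # 454.18121
#' @export
remnant_delta_mass <- function(sequence, pyro = FALSE, table = aa_mass_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  m <- sum(.residue_masses(sequence, table))
  if (isTRUE(pyro)) m <- m - table$ammonia
  m
}

#' m/z of an a/b/y fragment ion of a remnant sequence
#'
#' @param sequence Residue string fragmented as a linear peptide.
#' @param series One of `"a"`, `"b"`, `"y"`.
#' @param index Fragment index, `1 <= index < nchar(sequence)`.
#' @param charge Positive integer charge state.
#' @param table An [aa_mass_table()].
#' @return m/z in Th.
#' @export
fragment_ion_mz <- function(sequence, series = c("b", "y", "a"), index,
                            charge = 1L, table = aa_mass_table()) {
  series <- match.arg(series)
  n <- nchar(sequence)
  if (!(index >= 1L && index < n)) stop("fragment index out of range")
  if (charge < 1L) stop("charge must be a positive integer")
  masses <- .residue_masses(sequence, table)
  if (series == "y") {
    (sum(masses[(n - index + 1L):n]) + table$water + table$proton * charge) / charge
  } else {
    b <- (sum(masses[1:index]) + table$proton * charge) / charge
    if (series == "a") b - table$carbon_monoxide / charge else b
  }
}

#' ppm tolerance window around a mass
#'
#' @param mass Mass in Da, must be positive.
#' @param ppm Tolerance in parts per million, non-negative.
#' @return Numeric vector `c(low, high)`.
#' @export
tolerance_window <- function(mass, ppm) {
  if (any(mass <= 0)) stop("mass must be positive")
  if (any(ppm < 0)) stop("ppm must be non-negative")
  hw <- mass * ppm * 1e-6
  c(low = mass - hw, high = mass + hw)
}

#' Diagnostic ion m/z values for a remnant footprint
#'
#' Singly charged b, y and a ions over all fragment indices of the remnant
#' sequence plus the intact remnant `[M+H]+` (remnant treated as a free
#' peptide, so `[M+H]+` includes one water). The pyroglutamate flag
#' subtracts ammonia from every ion containing the N-terminal residue
#' (b/a series and the intact ion).
#'
#' @param sequence Remnant residue string.
#' @param pyro Logical pyroglutamate flag.
#' @param series Character vector of ion series to include.
#' @param include_intact Include the intact `[M+H]+` ion.
#' @param table An [aa_mass_table()].
#' @return Sorted numeric vector of m/z values.
#' @export
remnant_diagnostic_ions <- function(sequence, pyro = FALSE,
                                    series = c("b", "y", "a"),
                                    include_intact = TRUE,
                                    table = aa_mass_table()) {
  n <- nchar(sequence)
  stopifnot(n >= 2L)
  mz <- numeric(0)
  for (s in series) {
    for (i in seq_len(n - 1L)) {
      m <- fragment_ion_mz(sequence, s, i, 1L, table)
      if (pyro && s %in% c("a", "b")) m <- m - table$ammonia
      mz <- c(mz, m)
    }
  }
  if (include_intact) {
    m <- sum(.residue_masses(sequence, table)) + table$water + table$proton
    if (pyro) m <- m - table$ammonia
    mz <- c(mz, m)
  }
  sort(unique(mz))
}

#' Diagnostic m/z windows for a footprint at a ppm tolerance
#'
#' @inheritParams remnant_diagnostic_ions
#' @param ppm Tolerance applied to each ion (the pipeline default is each
#'   dataset's precursor tolerance).
#' @return Two-column matrix with columns `low`, `high`, one row per ion.
#' @export
diagnostic_windows <- function(sequence, ppm, pyro = FALSE,
                               series = c("b", "y", "a"),
                               include_intact = TRUE,
                               table = aa_mass_table()) {
  mz <- remnant_diagnostic_ions(sequence, pyro, series, include_intact, table)
  hw <- mz * ppm * 1e-6
  cbind(low = mz - hw, high = mz + hw)
}

#' Built-in SUMO remnant footprint definitions
#'
#' The footprints searched across the reanalyzed datasets: the SUMO-2
#' tryptic remnant QQTGG and its pyroglutamate form, the SUMO-3 remnant
#' NQTGG, the endogenous SUMO2/3 Asp-N remnant DVFQQQTGG, and the
#' Lys-C/Glu-C diGly remnant shared with ubiquitin.
#'
#' @return data.frame with columns `name`, `sequence`, `pyro`, `delta_mass`.
#' @export
remnant_footprints <- function() {
  df <- data.frame(
    name = c("QQTGG", "pyro-QQTGG", "NQTGG", "DVFQQQTGG", "diGly"),
    sequence = c("QQTGG", "QQTGG", "NQTGG", "DVFQQQTGG", "GG"),
    pyro = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  df$delta_mass <- mapply(remnant_delta_mass, df$sequence, df$pyro)
  df
}
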