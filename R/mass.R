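# Monoisotopic peptide mass utilities.
#
# Residue masses are the standard monoisotopic values for the 20 canonical
# amino-acid residues (i.e. the amino acid minus water); a free peptide adds
# one water, and [M+H]+ adds one proton.

# monoisotopic residue masses, Da
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER  <- 18.010565
.MASS_PROTON <- 1.007276

.check_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(.RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop(sprintf("non-canonical residue '%s' at position %d", res[bad[1]],
                 bad[1]), call. = FALSE)
  }
  res
}

#' Monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da),
#' assuming a free N-terminal amine and free C-terminal acid with no
#' modifications.
#'
#' @param sequence Single amino-acid string over the 20 canonical residues.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("YGGFMRRV")
monoisotopic_mass <- function(sequence) {
  res <- .check_peptide(sequence)
  sum(.RESIDUE_MASS[res]) + .MASS_WATER
}

#' Monoisotopic \[M+H\]+ of a peptide
#'
#' [monoisotopic_mass()] plus one proton (1.007276 Da): the singly
#' protonated ion mass observed in positive-mode MALDI-TOF.
#'
#' @inheritParams monoisotopic_mass
#' @return \[M+H\]+ in Da.
#' @export
#' @examples
#' mh_plus("YGGFMRRVGRPEW")
mh_plus <- function(sequence) {
  monoisotopic_mass(sequence) + .MASS_PROTON
}

#' Mass table for a set of peptides
#'
#' @param sequences Named character vector of peptide sequences.
#' @return data.frame with columns `id`, `sequence`, `monoisotopic`,
#'   `mh_plus`.
#' @export
peptide_mass_table <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("peptide_", seq_along(sequences))
  data.frame(
    id = ids,
    sequence = unname(sequences),
    monoisotopic = vapply(sequences, monoisotopic_mass, numeric(1),
                          USE.NAMES = FALSE),
    mh_plus = vapply(sequences, mh_plus, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
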