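# Monoisotopic and average residue masses (Da) for the 20 proteinogenic
# amino acids, from IUPAC/CODATA atomic masses. Residue = amino acid - water.
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

AA_AVG <- c(
  G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152,
  V = 99.1311, T = 101.1039, C = 103.1429, L = 113.1576,
  I = 113.1576, N = 114.1026, D = 115.0874, Q = 128.1292,
  K = 128.1723, E = 129.1140, M = 131.1961, H = 137.1393,
  F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099
)

WATER_MONO <- 18.0105646863
WATER_AVG <- 18.01528
PROTON_MASS <- 1.00727646688

AA_ALPHABET <- names(AA_MONO)

validate_sequence <- function(seq, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seq)
  if (any(bad)) {
    offenders <- unique(unlist(strsplit(
      gsub(sprintf("[%s]", paste(AA_ALPHABET, collapse = "")), "", seq[bad]), ""
    )))
    stop(sprintf(
      "invalid residue(s) %s in %s", paste(sQuote(offenders), collapse = ", "),
      what
    ), call. = FALSE)
  }
  invisible(seq)
}

residue_mass_sum <- function(seq, table) {
  vapply(strsplit(seq, ""), function(aa) sum(table[aa]), numeric(1))
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, for neutral peptides.
#' Masses are additive: `mass(paste0(a, b)) == mass(a) + mass(b) - water`.
#'
#' @param peptide_seq Character vector of peptide sequences using the
#'   20-letter amino-acid alphabet.
#' @return Numeric vector of monoisotopic masses in Daltons.
#' @examples
#' peptide_monoisotopic_mass("PEPTIDE")
#' @export
peptide_monoisotopic_mass <- function(peptide_seq) {
  stopifnot(is.character(peptide_seq))
  if (any(!nzchar(peptide_seq))) {
    stop("empty peptide sequence has no defined mass", call. = FALSE)
  }
  validate_sequence(peptide_seq, "peptide")
  residue_mass_sum(peptide_seq, AA_MONO) + WATER_MONO
}

#' Average (chemical) mass of a protein, in kDa
#'
#' Sum of residue average masses plus one water, reported in kilodaltons as
#' gel-scale masses are. Average rather than monoisotopic masses are used
#' because electrophoretic apparent masses are compared on the average scale.
#'
#' @param sequence Character vector of protein sequences.
#' @return Numeric vector of average masses in kDa.
#' @examples
#' protein_average_mass("G")  # 0.0751 kDa
#' @export
protein_average_mass <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(!nzchar(sequence))) {
    stop("empty protein sequence has no defined mass", call. = FALSE)
  }
  validate_sequence(sequence, "protein")
  (residue_mass_sum(sequence, AA_AVG) + WATER_AVG) / 1000
}

#' Calculated mass of an n-mer assembly
#'
#' Mass expected for an oligomer of `n_subunits` identical subunits, e.g. the
#' ~850 kDa reference line for a tetrameric channel whose subunit is ~212 kDa.
#'
#' @param sequence Subunit protein sequence.
#' @param n_subunits Number of subunits (>= 1).
#' @return Oligomer mass in kDa.
#' @export
oligomer_mass <- function(sequence, n_subunits) {
  if (!is.numeric(n_subunits) || any(n_subunits < 1) ||
      any(n_subunits != round(n_subunits))) {
    stop("`n_subunits` must be a positive integer", call. = FALSE)
  }
  n_subunits * protein_average_mass(sequence)
}

#' Mass-to-charge ratio of a peptide ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
mz_from_mass <- function(mass, charge) {
  stopifnot(all(charge >= 1), all(charge == round(charge)))
  (mass + charge * PROTON_MASS) / charge
}

#' Signed mass-measurement error in parts per million
#'
#' @param observed,theoretical m/z values (Th).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
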