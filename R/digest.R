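#' Digestion parameters
#'
#' Settings for in-silico tryptic digestion: the number of missed cleavages
#' tolerated and the peptide mass window considered observable by MS1.
#' Defaults mirror a typical high-resolution MS1 setup: one missed cleavage,
#' 700-3500 Da.
#'
#' @param missed_cleavages Non-negative integer.
#' @param min_mass,max_mass Monoisotopic mass window in Da, `min_mass < max_mass`.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(missed_cleavages = 1, min_mass = 700, max_mass = 3500) {
  stopifnot(
    is.numeric(missed_cleavages), missed_cleavages >= 0,
    missed_cleavages == round(missed_cleavages),
    is.numeric(min_mass), is.numeric(max_mass)
  )
  if (!(min_mass < max_mass)) stop("min_mass must be < max_mass", call. = FALSE)
  structure(
    list(
      missed_cleavages = as.integer(missed_cleavages),
      min_mass = min_mass, max_mass = max_mass
    ),
    class = "digest_params"
  )
}

# Indices i such that trypsin cleaves between residue i and i+1:
# after K or R, never before P.
cleavage_sites <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2) return(integer(0))
  i <- which(aa[-n] %in% c("K", "R"))
  i[aa[i + 1] != "P"]
}

#' In-silico tryptic digestion
#'
#' Fully tryptic peptides of a protein sequence (cleavage after K/R, not
#' before P) with up to `missed_cleavages` internal sites retained, filtered
#' to the monoisotopic mass window. Peptides are returned in order of first
#' occurrence; a peptide generated more than once (repeated subsequence)
#' appears once with its occurrence count.
#'
#' @param sequence Protein sequence (20-letter alphabet). An empty string
#'   yields an empty result.
#' @param params A [digest_params()] object.
#' @return A tibble with columns `peptide_seq`, `n_missed`, `mass`
#'   (monoisotopic, Da) and `count`.
#' @export
tryptic_digest <- function(sequence, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"), is.character(sequence),
            length(sequence) == 1)
  empty <- tibble::tibble(
    peptide_seq = character(), n_missed = integer(),
    mass = numeric(), count = integer()
  )
  if (!nzchar(sequence)) return(empty)
  validate_sequence(sequence, "protein")

  sites <- cleavage_sites(sequence)
  bounds <- c(0L, sites, nchar(sequence))  # fragment i = (bounds[i], bounds[i+1]]
  n_frag <- length(bounds) - 1L
  out <- purrr::map_dfr(seq_len(n_frag), function(i) {
    j_max <- min(n_frag, i + params$missed_cleavages)
    purrr::map_dfr(i:j_max, function(j) {
      tibble::tibble(
        peptide_seq = substr(sequence, bounds[i] + 1L, bounds[j + 1L]),
        n_missed = j - i
      )
    })
  })
  out$mass <- peptide_monoisotopic_mass(out$peptide_seq)
  out <- dplyr::filter(out, .data$mass >= params$min_mass,
                       .data$mass <= params$max_mass)
  if (nrow(out) == 0) return(empty)
  out |>
    dplyr::group_by(.data$peptide_seq) |>
    dplyr::summarise(
      n_missed = min(.data$n_missed), mass = .data$mass[1],
      count = dplyr::n(), .groups = "drop"
    ) |>
    # restore order of first occurrence
    dplyr::arrange(match(.data$peptide_seq, out$peptide_seq)) |>
    dplyr::select("peptide_seq", "n_missed", "mass", "count")
}

#' Number of MS-accessible peptides of a protein
#'
#' The count of distinct fully tryptic peptides (at up to the allowed missed
#' cleavages) whose monoisotopic mass falls inside the observable mass
#' window. This is the denominator of the abundance-norm value: a protein's
#' summed peak volume divided by how many peptides the instrument could in
#' principle have seen gives a molar-abundance estimate comparable across
#' proteins of different size.
#'
#' @inheritParams tryptic_digest
#' @return A single non-negative integer.
#' @export
n_ms_accessible_peptides <- function(sequence, params = digest_params()) {
  nrow(tryptic_digest(sequence, params))
}

#' MS-accessible peptide counts for a sequence table
#'
#' @param sequences A tibble with columns `protein_id` and `sequence`.
#' @param params A [digest_params()] object.
#' @return A tibble `protein_id`, `n_accessible`.
#' @export
accessible_peptide_counts <- function(sequences, params = digest_params()) {
  stopifnot(all(c("protein_id", "sequence") %in% names(sequences)))
  tibble::tibble(
    protein_id = sequences$protein_id,
    n_accessible = vapply(sequences$sequence, n_ms_accessible_peptides,
                          integer(1), params = params, USE.NAMES = FALSE)
  )
}
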