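# Independent oracles, deliberately written without reusing package
# internals: their own residue-mass table and a brute-force enumeration of
# tryptic cleavage products.

ORACLE_MONO <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414
)
ORACLE_WATER <- 18.0105646863

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_MONO[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

# Brute force: cut positions are after K/R not followed by P; a peptide with
# <= m missed cleavages spans m+1 consecutive fragments.
oracle_digest <- function(seq, missed = 0, min_mass = 0, max_mass = Inf) {
  if (!nzchar(seq)) return(character(0))
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  cuts <- integer(0)
  for (i in seq_len(max(0, n - 1))) {
    if (aa[i] %in% c("K", "R") && aa[i + 1] != "P") cuts <- c(cuts, i)
  }
  bounds <- c(0, cuts, n)
  peps <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(length(bounds) - 1, i + missed)) {
      peps <- c(peps, substr(seq, bounds[i] + 1, bounds[j + 1]))
    }
  }
  peps <- unique(peps)
  masses <- vapply(peps, oracle_peptide_mass, numeric(1))
  peps[masses >= min_mass & masses <= max_mass]
}

random_aa_sequence <- function(len) {
  paste(sample(names(ORACLE_MONO), len, replace = TRUE), collapse = "")
}

# Small single-run feature tibble with explicit values, for I/O and
# assignment fixtures.
make_run <- function(features, run_id = "r1", antibody = "ab1",
                     sample_class = "target_ap", detergent = "CL-47") {
  dplyr::bind_cols(
    tibble::tibble(
      run_id = run_id, antibody = antibody, sample_class = sample_class,
      detergent = detergent, species_source = "test"
    )[rep(1, nrow(features)), ],
    features
  )
}

# Compact simulated study shared across alignment/quantification tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_apms_study(ap_sim_config(
        n_background_proteins = 60, n_tuc_controls = 3,
        n_antibodies_target = 3, seed = 101
      ))
    }
    cache
  }
})
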