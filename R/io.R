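SAMPLE_CLASSES <- c("target_ap", "tuc_control", "ko_control")
DETERGENTS <- c("CL-47", "CL-91")

FEATURE_COLUMNS <- c(
  "protein_id", "peptide_seq", "charge",
  "mz_theoretical", "mz_observed", "rt", "pv"
)
META_FIELDS <- c("run_id", "antibody", "sample_class", "detergent",
                 "species_source")

# Full-precision, exponent-safe float formatting so written tables re-read
# to bit-identical doubles.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a single-run MS1 feature table
#'
#' Feature tables are UTF-8 tab-separated text. Run metadata (run id,
#' antibody, sample class, solubilisation detergent, species source) is
#' carried in leading `# key: value` lines; the body has one row per MS1
#' feature with columns `protein_id`, `peptide_seq`, `charge`,
#' `mz_theoretical`, `mz_observed`, `rt` (minutes) and `pv` (peak volume).
#'
#' Rows that fail validation (unparsable numbers, invalid peptide characters,
#' non-positive m/z, negative peak volume or retention time) are dropped with
#' a warning that names the offending row numbers. Unknown `sample_class` or
#' `detergent` values are file-level errors: those vocabularies are closed.
#'
#' @param path Path to a feature-table file.
#' @return A tibble with the metadata fields as leading columns, one row per
#'   retained feature.
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  meta_lines <- lines[meta_idx]
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(body)]

  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  missing_meta <- setdiff(META_FIELDS, names(meta))
  if (length(missing_meta) > 0) {
    stop(sprintf("feature table %s is missing metadata field(s): %s",
                 path, paste(missing_meta, collapse = ", ")), call. = FALSE)
  }
  if (!meta$sample_class %in% SAMPLE_CLASSES) {
    stop(sprintf(
      "unknown sample_class %s (must be one of %s)",
      sQuote(meta$sample_class), paste(SAMPLE_CLASSES, collapse = ", ")
    ), call. = FALSE)
  }
  if (!meta$detergent %in% DETERGENTS) {
    stop(sprintf(
      "unknown detergent %s (must be one of %s)",
      sQuote(meta$detergent), paste(DETERGENTS, collapse = ", ")
    ), call. = FALSE)
  }

  if (length(body) == 0) {
    stop(sprintf("feature table %s has no header line", path), call. = FALSE)
  }
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  missing_col <- setdiff(FEATURE_COLUMNS, header)
  if (length(missing_col) > 0) {
    stop(sprintf("feature table %s is missing column(s): %s",
                 path, paste(missing_col, collapse = ", ")), call. = FALSE)
  }

  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  feat <- empty_feature_tibble()
  bad_rows <- integer(0)
  if (length(rows) > 0) {
    mat <- do.call(rbind, lapply(rows, function(r) {
      length(r) <- length(header)
      r
    }))
    colnames(mat) <- header
    df <- tibble::as_tibble(mat)[FEATURE_COLUMNS]
    num <- suppressWarnings(dplyr::mutate(
      df,
      charge = as.numeric(.data$charge),
      mz_theoretical = as.numeric(.data$mz_theoretical),
      mz_observed = as.numeric(.data$mz_observed),
      rt = as.numeric(.data$rt),
      pv = as.numeric(.data$pv)
    ))
    valid_seq <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")),
                       num$peptide_seq)
    ok <- valid_seq &
      !is.na(num$charge) & num$charge >= 1 & num$charge == round(num$charge) &
      !is.na(num$mz_theoretical) & num$mz_theoretical > 0 &
      !is.na(num$mz_observed) & num$mz_observed > 0 &
      !is.na(num$rt) & num$rt >= 0 &
      !is.na(num$pv) & is.finite(num$pv) & num$pv >= 0
    bad_rows <- which(!ok)
    feat <- num[ok, ]
    feat$charge <- as.integer(feat$charge)
  }
  if (length(bad_rows) > 0) {
    warning(sprintf(
      "%s: rejected %d malformed feature row(s) at line(s) %s",
      path, length(bad_rows),
      paste(utils::head(bad_rows, 20), collapse = ", ")
    ), call. = FALSE)
  }

  dplyr::bind_cols(
    tibble::as_tibble(meta[META_FIELDS])[rep(1, nrow(feat)), ],
    feat
  )
}

empty_feature_tibble <- function() {
  tibble::tibble(
    protein_id = character(), peptide_seq = character(), charge = integer(),
    mz_theoretical = numeric(), mz_observed = numeric(),
    rt = numeric(), pv = numeric()
  )
}

#' Write a single-run MS1 feature table
#'
#' Inverse of [read_feature_table()]: metadata as `# key: value` lines, then
#' a fixed-order tab-separated body with full-precision floats, so that a
#' write/read round trip reproduces the table exactly.
#'
#' @param table A single-run feature tibble (all metadata columns constant).
#' @param path Output path.
#' @param meta Optional named list giving the run metadata; required only
#'   when `table` has no rows to infer it from.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, meta = NULL) {
  stopifnot(all(c(META_FIELDS, FEATURE_COLUMNS) %in% names(table)))
  for (f in c("run_id", "antibody", "sample_class", "detergent")) {
    if (nrow(table) > 0 && dplyr::n_distinct(table[[f]]) != 1) {
      stop(sprintf("write_feature_table() writes one run; %s is not constant", f),
           call. = FALSE)
    }
  }
  if (nrow(table) > 0) {
    meta <- table[1, META_FIELDS]
  } else if (!is.null(meta) && all(META_FIELDS %in% names(meta))) {
    meta <- tibble::as_tibble(meta[META_FIELDS])
  } else {
    stop("cannot infer run metadata from an empty table; ",
         "pass `meta` with fields ", paste(META_FIELDS, collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", META_FIELDS, unlist(meta[1, ])), con)
  writeLines(paste(FEATURE_COLUMNS, collapse = "\t"), con)
  feat <- table[FEATURE_COLUMNS]
  if (nrow(feat) > 0) {
    body <- paste(
      feat$protein_id, feat$peptide_seq, as.integer(feat$charge),
      format_num(feat$mz_theoretical), format_num(feat$mz_observed),
      format_num(feat$rt), format_num(feat$pv),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a study directory of feature tables
#'
#' @param paths Character vector of feature-table paths.
#' @return One long tibble with all runs stacked.
#' @export
read_study <- function(paths) {
  purrr::map_dfr(paths, read_feature_table)
}

#' Read protein sequences from FASTA
#'
#' Standard multi-line FASTA; sequences are uppercased and trailing `*` stop
#' characters stripped. A record containing characters outside the 20-letter
#' amino-acid alphabet is an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id` (first header token),
#'   `description` (remainder of header) and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("failed to parse FASTA %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  headers <- names(set)
  seqs <- unname(toupper(as.character(set)))
  seqs <- sub("\\*+$", "", seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    stop(sprintf("FASTA record(s) with non-amino-acid characters: %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop(sprintf("FASTA record(s) with empty sequence: %s",
                 paste(ids[!nzchar(seqs)], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(protein_id = ids, description = desc, sequence = seqs)
}

#' Write protein sequences to FASTA
#'
#' @param sequences Tibble with `protein_id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(sequences)))
  desc <- if ("description" %in% names(sequences)) sequences$description else ""
  headers <- ifelse(nzchar(desc),
                    paste(sequences$protein_id, desc),
                    sequences$protein_id)
  set <- Biostrings::BStringSet(sequences$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a protein-by-slice peak-volume matrix
#'
#' Wide TSV with a `protein_id` column and slice columns `slice_0001` ...
#' `slice_N`, returned in long (tidy) form.
#'
#' @param path Path to the matrix TSV.
#' @return A tibble `protein_id`, `slice` (integer), `pv`.
#' @export
read_slice_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df)) {
    stop("slice matrix is missing the protein_id column", call. = FALSE)
  }
  slice_cols <- grep("^slice_\\d+$", names(df), value = TRUE)
  if (length(slice_cols) == 0) stop("no slice_* columns found", call. = FALSE)
  tibble::as_tibble(df) |>
    tidyr::pivot_longer(dplyr::all_of(slice_cols),
                        names_to = "slice", values_to = "pv") |>
    dplyr::mutate(slice = as.integer(sub("^slice_", "", .data$slice))) |>
    dplyr::arrange(.data$protein_id, .data$slice)
}

#' Write a protein-by-slice peak-volume matrix
#'
#' @param profiles Long tibble `protein_id`, `slice`, `pv`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_slice_matrix <- function(profiles, path) {
  stopifnot(all(c("protein_id", "slice", "pv") %in% names(profiles)))
  n <- max(profiles$slice)
  wide <- profiles |>
    dplyr::mutate(slice = sprintf("slice_%04d", .data$slice)) |>
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "slice",
                       values_from = "pv", values_fill = 0)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
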