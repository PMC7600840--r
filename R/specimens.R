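#' Compute the three malar ratio statistics
#'
#' Derives the size-invariant ratios used throughout the package from raw
#' reticle measurements:
#' MRL = malar length / malar width,
#' MR1 = malar length / flagellomere-1 length,
#' MR3 = malar length / flagellomere-3 length.
#' Reticle units are arbitrary and never converted to millimetres; because
#' all four measurements of one specimen share the same reticle scale, the
#' ratios are unit-free and scale-invariant.
#'
#' In bees of this species group the malar length is empirically smaller
#' than the malar width, so `mrl < 1` is expected; a ratio at or above 1 is
#' reported as a warning (it may indicate swapped measurements) but is not
#' an error.
#'
#' @param records specimen data frame with positive numeric columns
#'   `malar_length`, `malar_width`, `flag1_length`, `flag3_length`.
#' @return `records` with numeric columns `mr1`, `mr3`, `mrl` appended
#'   (existing ratio columns are overwritten).
#' @examples
#' df <- data.frame(malar_length = 0.92, malar_width = 1,
#'                  flag1_length = 0.6301, flag3_length = 0.5027)
#' compute_ratios(df)[, c("mrl", "mr1", "mr3")]
#' @export
compute_ratios <- function(records) {
  stopifnot(is.data.frame(records))
  meas <- c("malar_length", "malar_width", "flag1_length", "flag3_length")
  missing_cols <- setdiff(meas, names(records))
  if (length(missing_cols)) {
    stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (m in meas) {
    v <- records[[m]]
    if (!is.numeric(v)) stop(sprintf("column '%s' must be numeric", m), call. = FALSE)
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("column '%s': non-positive or missing value (row %s)",
                   m, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  records$mr1 <- records$malar_length / records$flag1_length
  records$mr3 <- records$malar_length / records$flag3_length
  records$mrl <- records$malar_length / records$malar_width
  n_big <- sum(records$mrl >= 1)
  if (n_big > 0) {
    warning(sprintf(
      "%d record(s) have mrl >= 1 (malar length not smaller than width); unusual for this species group",
      n_big), call. = FALSE)
  }
  records
}

#' Read and validate a specimen measurement table
#'
#' Reads a UTF-8 comma-separated specimen table with one row per bee.
#' Required columns: `id`, `species_dna`, `caste`, `region`, `malar_length`,
#' `malar_width`, `flag1_length`, `flag3_length`. Recognised optional
#' columns: `species_visual`, `observer`, `mesipisternum`, `scutum_black`,
#' `t5_yellow`, `t3_yellow`. Closed-vocabulary fields are normalised
#' case-insensitively; unrecognised values raise an error naming the column
#' and row. Males are out of scope (they are identifiable with standard
#' keys), so `caste` must be `queen` or `worker`. Extra columns are kept but
#' reported with a message.
#'
#' @param path path to a CSV file.
#' @param ... further arguments passed to [utils::read.csv()].
#' @return a validated specimen data frame (ratio columns not yet computed;
#'   see [compute_ratios()]).
#' @seealso [write_specimen_table()] for the inverse; reading a written
#'   table reproduces the records (round-trip identity).
#' @export
read_specimen_table <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, ...)
  required <- c("id", "species_dna", "caste", "region",
                "malar_length", "malar_width", "flag1_length", "flag3_length")
  optional <- c("species_visual", "observer",
                "mesipisternum", "scutum_black", "t5_yellow", "t3_yellow")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    message("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }

  df$id <- as.character(df$id)
  df$species_dna <- .normalize_vocab(df$species_dna, .bombus_species, "species_dna")
  if ("species_visual" %in% names(df)) {
    df$species_visual <- .normalize_vocab(df$species_visual, .bombus_species,
                                          "species_visual")
  }
  df$caste  <- .normalize_vocab(df$caste, .bombus_castes, "caste",
                                allow_unknown = FALSE)
  df$region <- .normalize_vocab(df$region, .bombus_regions, "region",
                                allow_unknown = FALSE)
  if ("mesipisternum" %in% names(df)) {
    df$mesipisternum <- .normalize_vocab(df$mesipisternum, .mesi_levels,
                                         "mesipisternum")
  }
  for (col in c("scutum_black", "t5_yellow")) {
    if (col %in% names(df)) {
      df[[col]] <- .normalize_vocab(df[[col]], .abund_levels, col)
    }
  }
  if ("t3_yellow" %in% names(df)) df$t3_yellow <- as.logical(df$t3_yellow)

  for (m in c("malar_length", "malar_width", "flag1_length", "flag3_length")) {
    v <- df[[m]]
    if (!is.numeric(v)) stop(sprintf("column '%s' must be numeric", m), call. = FALSE)
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("column '%s': non-positive or missing value (row %s)",
                   m, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Write a specimen table to CSV
#'
#' @param records specimen data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Agreement between field (visual) and DNA-confirmed identifications
#'
#' Fraction of specimens whose pre-DNA visual identification
#' (`species_visual`, from keys and hair-colour characters) matches the
#' DNA-barcode identification (`species_dna`). Records with either label
#' missing or `unknown` are an error rather than silently dropped.
#'
#' @param records specimen data frame with `species_visual` and
#'   `species_dna` columns.
#' @return proportion in \[0, 1\].
#' @export
visual_agreement <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (!"species_visual" %in% names(records)) {
    stop("records carry no 'species_visual' column", call. = FALSE)
  }
  vis <- records$species_visual
  dna <- records$species_dna
  if (any(is.na(vis) | vis == "unknown" | is.na(dna) | dna == "unknown")) {
    stop("all records must have known species_visual and species_dna",
         call. = FALSE)
  }
  mean(vis == dna)
}
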