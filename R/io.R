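#' Read a biomarker concentration table
#'
#' Reads a CSV/TSV of absolute biomarker concentrations (one row per
#' sample measurement). Two header dialects are supported:
#'
#' * `tidy` — columns are catalog biomarker names plus a `sample_id`
#'   column (created from the first column if absent).
#' * `showcase` — column headers are biobank showcase field IDs (for
#'   example `23474-0.0`), mapped to catalog names through a lookup
#'   table. The lookup shipped with the package
#'   (`ukb_showcase_field_map_synthetic.tsv`) is a constructed
#'   placeholder, not the official field assignment; replace it via
#'   `field_map` for real showcase extracts.
#'
#' Empty cells become missing values. Negative or non-numeric cells are
#' fatal, reported with their row and column. Unknown columns are kept
#' but reported via a message.
#'
#' @param path CSV or TSV file ('.' decimal separator, UTF-8).
#' @param dialect `"tidy"` or `"showcase"`.
#' @param catalog An [nmr_catalog()].
#' @param field_map For the showcase dialect: a data frame with columns
#'   `field_id` and `name`, defaulting to the shipped synthetic lookup.
#' @return A tibble with `sample_id` and numeric biomarker columns.
#' @export
read_biomarker_table <- function(path, dialect = c("tidy", "showcase"),
                                 catalog = NULL, field_map = NULL) {
  dialect <- match.arg(dialect)
  catalog <- catalog %||% nmr_catalog()
  raw <- read_delim_auto(path)
  if (dialect == "showcase") {
    field_map <- field_map %||% readr::read_tsv(
      system.file("extdata", "ukb_showcase_field_map_synthetic.tsv",
                  package = "nmrplateqc", mustWork = TRUE),
      col_types = "cc", progress = FALSE)
    stripped <- sub("-.*$", "", names(raw))
    hit <- match(stripped, field_map$field_id)
    names(raw)[!is.na(hit)] <- field_map$name[hit[!is.na(hit)]]
  }
  if (!"sample_id" %in% names(raw)) {
    names(raw)[1] <- "sample_id"
  }
  raw$sample_id <- as.character(raw$sample_id)
  known <- intersect(names(raw), catalog$name)
  unknown <- setdiff(names(raw), c("sample_id", catalog$name))
  if (length(unknown)) {
    inform(paste0("ignoring ", length(unknown), " column(s) not in the ",
                  "catalog: ", paste(head(unknown, 8), collapse = ", "),
                  if (length(unknown) > 8) ", ..."))
  }
  for (bm in known) {
    v <- raw[[bm]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad)) {
      abort(paste0("non-numeric value in row ", bad[1], ", column ", bm,
                   ": '", v[bad[1]], "'"))
    }
    neg <- which(!is.na(num) & num < 0)
    if (length(neg)) {
      abort(paste0("negative concentration in row ", neg[1], ", column ",
                   bm, ": ", num[neg[1]]))
    }
    if (any(!is.finite(num) & !is.na(num))) {
      abort(paste0("non-finite value in column ", bm))
    }
    raw[[bm]] <- num
  }
  as_tibble(raw[c("sample_id", known, unknown)])
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim,
                    col_types = readr::cols(.default = "c"),
                    na = c("", "NA"), progress = FALSE)
}

#' Read a sample technical-metadata table
#'
#' @param path CSV/TSV with columns `sample_id`, `plate_id`, `well_row`,
#'   `well_col`, `spectrometer_id`, `prep_timestamp`,
#'   `measurement_timestamp` and optionally `is_control_well`,
#'   `shipping_batch`, `robot`, `tip`.
#' @return A validated tibble with parsed timestamps.
#' @export
read_sample_metadata <- function(path) {
  raw <- read_delim_auto(path)
  check_meta(raw)
  raw$well_col <- as.integer(raw$well_col)
  raw$prep_timestamp <- to_posix(raw$prep_timestamp)
  raw$measurement_timestamp <- to_posix(raw$measurement_timestamp)
  if ("is_control_well" %in% names(raw)) {
    raw$is_control_well <- as.logical(raw$is_control_well)
  }
  as_tibble(raw)
}

#' Read a blind-duplicate linkage table
#'
#' @param path CSV/TSV with columns `group_id`, `sample_id` and
#'   optionally `release`.
#' @return A validated tibble.
#' @export
read_duplicate_table <- function(path) {
  raw <- read_delim_auto(path)
  if ("release" %in% names(raw)) raw$release <- as.logical(raw$release)
  check_duplicates(raw)
}

#' Write a QC result and its audit logs to a directory
#'
#' Writes `postqc.csv` (all biomarker columns in catalog order),
#' `offsets.csv` (the offset ledger), `coefficients.csv` (every fitted
#' term of every adjustment step), `bins.csv` (the plate date-bin map)
#' and `outlier_plates.csv`. Numbers are written with shortest
#' round-trip representations; reading the files back reproduces the
#' values to full double precision and the missingness pattern exactly.
#'
#' @param qc An `nmr_qc` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qc_result <- function(qc, dir) {
  stopifnot(inherits(qc, "nmr_qc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    postqc = file.path(dir, "postqc.csv"),
    offsets = file.path(dir, "offsets.csv"),
    coefficients = file.path(dir, "coefficients.csv"),
    bins = file.path(dir, "bins.csv"),
    outlier_plates = file.path(dir, "outlier_plates.csv")
  )
  readr::write_csv(qc$postqc, paths["postqc"], na = "", progress = FALSE)
  readr::write_csv(qc$offsets, paths["offsets"], na = "", progress = FALSE)
  readr::write_csv(qc$coefficients, paths["coefficients"], na = "",
                   progress = FALSE)
  readr::write_csv(qc$bin_map, paths["bins"], na = "", progress = FALSE)
  outliers <- qc$outlier_report %||%
    tibble(biomarker = character(), plate_id = character())
  readr::write_csv(outliers, paths["outlier_plates"], na = "",
                   progress = FALSE)
  invisible(paths)
}
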