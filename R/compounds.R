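#' Read a compound table
#'
#' Reads the CSV describing the study compounds: identity, literature logP,
#' one or two basic-site pKa values, a role in the workflow (`model`
#' compounds parameterise the QSRR fits, `verification` compounds are held
#' out for external validation, `sample` compounds are the unknowns whose
#' logD is predicted), and optional molecular descriptors.
#'
#' Expected columns: `id,name,logP,pKa1,pKa2,role` plus optional `A`, `B`
#' (hydrogen-bond acidity/basicity) and optional per-pH electrostatic-charge
#' columns `ne_<pH>` (e.g. `ne_7`).  Empty cells are missing values.  Both
#' the ASCII hyphen-minus and the typographic minus sign (U+2212) are
#' accepted in numeric cells.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame of compounds.
#' @examples
#' comp <- read_compounds(chromlogd_example("study_compounds.csv"))
#' table(comp$role)
#' @export
read_compounds <- function(path) {
  df <- read_csv_ascii(path)
  required <- c("id", "name", "logP", "pKa1", "role")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("compound CSV ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"pKa2" %in% names(df)) df$pKa2 <- NA_real_
  df$id <- as.character(df$id)
  for (col in c("logP", "pKa1", "pKa2", "A", "B",
                grep("^ne_", names(df), value = TRUE))) {
    if (col %in% names(df)) df[[col]] <- parse_numeric(df[[col]], col, path)
  }
  validate_compounds(df)
}

#' Validate a compound table
#'
#' Checks the structural invariants of a compound table: unique ids, known
#' roles, `pKa2 < pKa1` where both are present, logP and pKa1 present for
#' every model and verification compound (only samples may lack a
#' literature logP), and non-negative `A`/`B` descriptors.
#'
#' @param df Data frame with at least `id`, `name`, `logP`, `pKa1`, `role`.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_compounds <- function(df) {
  dup <- duplicated(df$id)
  if (any(dup)) {
    stop("duplicate compound id(s): ",
         paste(unique(df$id[dup]), collapse = ", "), call. = FALSE)
  }
  bad_role <- !df$role %in% c("model", "verification", "sample")
  if (any(bad_role)) {
    stop("unknown role(s): ", paste(unique(df$role[bad_role]), collapse = ", "),
         " (expected model, verification or sample)", call. = FALSE)
  }
  both <- !is.na(df$pKa2) & !is.na(df$pKa1)
  if (any(both & df$pKa2 >= df$pKa1)) {
    stop("pKa2 must be smaller than pKa1 (compound ",
         paste(df$id[both & df$pKa2 >= df$pKa1], collapse = ", "), ")",
         call. = FALSE)
  }
  fit_roles <- df$role %in% c("model", "verification")
  incomplete <- fit_roles & (is.na(df$logP) | is.na(df$pKa1))
  if (any(incomplete)) {
    stop("model/verification compound(s) missing logP or pKa1: ",
         paste(df$id[incomplete], collapse = ", "), call. = FALSE)
  }
  for (col in c("A", "B")) {
    if (col %in% names(df) && any(df[[col]] < 0, na.rm = TRUE)) {
      stop("descriptor ", col, " must be non-negative", call. = FALSE)
    }
  }
  df
}

#' Write a compound table
#'
#' Inverse of [read_compounds()]; round-trips all columns.
#'
#' @param df Compound table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Path to a packaged example data set
#'
#' The package ships the study tables as plain-text fixtures:
#' `study_compounds.csv` (42 compounds with logP/pKa and roles),
#' `study_logkw.csv` (extrapolated logkw per compound per pH),
#' `study_logd_published.csv` (published logD of the 23 model compounds, for
#' cross-checking the ionization layer), `study_validation_published.csv` (external
#' validation of the multi-parameter models) and `study_sample_logd_published.csv`
#' (published sample predictions, comparison only).
#'
#' @param file File name within the package's `extdata` directory; when
#'   missing, lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
chromlogd_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "chromlogd")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop("no packaged file '", file, "'; see chromlogd_example() for the list",
         call. = FALSE)
  }
  path
}

## Shared CSV reading: UTF-8, '.' decimal separator, no factor coercion.
read_csv_ascii <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}

## Numeric parser that accepts the typographic minus (U+2212) used in the
## published tables and reports the offending row on failure.
parse_numeric <- function(x, col, path = "<data>") {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("\u2212", "-", trimws(as.character(x)))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop("malformed numeric cell in ", path, ", column '", col, "', row ",
         paste(bad, collapse = ", "), ": '", x[bad[1]], "'", call. = FALSE)
  }
  out
}
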