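#' Can a structure be modelled by the BCF QSARs?
#'
#' Mirrors the curation rule that removed inorganic chemicals, metal-organic
#' compounds, salts/mixtures and ions before modelling. A molecule is
#' modellable when it is a single covalently connected component, contains
#' at least one carbon, carries no net formal charge, and uses only the
#' organic element set (H, B, C, N, O, F, Si, P, S, Cl, Br, I); every other
#' element is treated as a metal/metalloid exclusion.
#'
#' @param m a `molecule`.
#' @return a list with `ok` (logical) and `reason` (`NA` when modellable,
#'   otherwise one of `"salt/mixture"`, `"metal-organic"`, `"ion"`,
#'   `"inorganic"`).
#' @examples
#' is_modellable(parse_smiles("CCO"))$ok
#' is_modellable(parse_smiles("[Na+].[Cl-]"))$reason
#' @export
is_modellable <- function(m) {
  stopifnot(inherits(m, "molecule"))
  res <- function(ok, reason = NA_character_) list(ok = ok, reason = reason)
  if (max(graph_components(m)) > 1L) return(res(FALSE, "salt/mixture"))
  if (any(!m$atoms$element %in% ORGANIC_ELEMENTS))
    return(res(FALSE, "metal-organic"))
  if (sum(m$atoms$charge) != 0L) return(res(FALSE, "ion"))
  if (!any(m$atoms$element == "C")) return(res(FALSE, "inorganic"))
  res(TRUE)
}

#' Read a BCF dataset from CSV
#'
#' Expects a header with columns `id` and `smiles`; any number of
#' `logbcf`-prefixed columns (e.g. `logbcf`, `logbcf_1`, `logbcf_2`) holding
#' replicate log BCF measurements (log10 L/kg), and an optional `class`
#' column with `B` / `not-B` labels. Rows whose SMILES fail to parse are
#' collected in a rejects report, never silently dropped.
#'
#' @param path path to a CSV file (RFC-4180, UTF-8, `.` decimal separator).
#' @return a list with `records` (list of `bcf_record`) and `rejects`
#'   (data frame with `row`, `id`, `reason`).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("dataset file is empty: ", path, call. = FALSE)
  required <- c("id", "smiles")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  value_cols <- grep("^logbcf", names(df), value = TRUE)
  has_class <- "class" %in% names(df)

  records <- list()
  rej_row <- integer(0); rej_id <- character(0); rej_reason <- character(0)
  for (r in seq_len(nrow(df))) {
    mol <- tryCatch(parse_smiles(df$smiles[r]), error = identity)
    if (inherits(mol, "error")) {
      rej_row <- c(rej_row, r)
      rej_id <- c(rej_id, as.character(df$id[r]))
      rej_reason <- c(rej_reason, conditionMessage(mol))
      next
    }
    vals <- unlist(df[r, value_cols, drop = FALSE], use.names = FALSE)
    vals <- as.numeric(vals[!is.na(vals)])
    records[[length(records) + 1L]] <- bcf_record(
      id = as.character(df$id[r]), smiles = df$smiles[r],
      logbcf_values = vals,
      class_label = if (has_class && !is.na(df$class[r]) &&
                        nzchar(df$class[r])) df$class[r] else NA_character_
    )
  }
  list(records = records,
       rejects = data.frame(row = rej_row, id = rej_id, reason = rej_reason,
                            stringsAsFactors = FALSE))
}

#' BCF record constructor
#'
#' One chemical: identifier, SMILES, replicate log BCF measurements, their
#' mean, and the regulatory class label when assigned (B iff mean
#' log BCF > 3.30).
#'
#' @param id identifier (CAS number or arbitrary key).
#' @param smiles SMILES text.
#' @param logbcf_values numeric vector of log BCF measurements (may be
#'   empty for prediction-only records).
#' @param class_label `"B"`, `"not-B"` or `NA`.
#' @return an object of class `bcf_record`.
#' @export
bcf_record <- function(id, smiles, logbcf_values = numeric(0),
                       class_label = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.na(class_label) && !class_label %in% c("B", "not-B"))
    stop("class_label must be 'B' or 'not-B'", call. = FALSE)
  structure(list(
    id = id, smiles = smiles,
    logbcf_values = as.numeric(logbcf_values),
    logbcf_mean = if (length(logbcf_values)) mean(logbcf_values) else NA_real_,
    class_label = class_label
  ), class = "bcf_record")
}

#' Write / read prediction tables
#'
#' `write_predictions()` writes a per-chemical prediction table to CSV;
#' `read_predictions()` reads it back. Numeric columns are written at full
#' precision so that a write/read round trip preserves ids and values.
#'
#' @param df data frame with at least an `id` column.
#' @param path output CSV path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns the data frame.
#' @export
write_predictions <- function(df, path) {
  stopifnot(is.data.frame(df), "id" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a rejects report (row, id, reason) to CSV
#' @param rejects data frame as returned by [read_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejects <- function(rejects, path) {
  utils::write.csv(rejects, path, row.names = FALSE)
  invisible(path)
}
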