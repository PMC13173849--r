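# PAH metadata table: schema, CSV ingest, ordinal carcinogenicity encoding,
# cross-validation against structures, and summaries.

#' Canonical column order of the PAH metadata table
#' @export
pah_table_columns <- c("id", "iupac_name", "xyz_file", "n_carbon", "n_hydrogen",
                       "bay", "fjord", "harbor", "canyon",
                       "topology", "carcinogenicity", "log_p", "log_iball")

#' Seven-level carcinogenicity vocabulary, in increasing potency order
#' @export
carcinogenicity_levels <- c("-", "±", "L", "LM", "M", "HM", "H")

# header synonyms for the deposited spreadsheet's likely column names;
# matching is on lowercased, non-alphanumeric-stripped headers
.column_synonyms <- list(
  id = c("id", "no", "index", "compound"),
  iupac_name = c("iupacname", "name", "iupac"),
  xyz_file = c("xyzfile", "pahxyzinputfile", "xyz", "file", "inputfile"),
  n_carbon = c("ncarbon", "carbon", "carbons", "c", "numberofcarbonatoms"),
  n_hydrogen = c("nhydrogen", "hydrogen", "hydrogens", "h", "numberofhydrogenatoms"),
  bay = c("bay", "b"),
  fjord = c("fjord", "f"),
  harbor = c("harbor", "harbour"),
  canyon = c("canyon"),
  topology = c("topology", "topologyclass", "fusedringtopology",
               "fusedbenzeneringtopology", "ringtopology"),
  carcinogenicity = c("carcinogenicity", "carcinogenicityclass", "activity",
                      "carcinogenicactivity"),
  log_p = c("logp"),
  log_iball = c("logiball", "logiballindex", "iball")
)

# Normalize a carcinogenicity cell: unicode dashes to "-", "+-"/"+/-" to the
# plus-minus sign, alias "+" to "LM". Returns the label (NA for blank) and
# whether the "+" alias fired.
normalize_carc_label <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || !nzchar(x)) return(list(label = NA_character_, aliased = FALSE))
  x <- gsub("[‒–—−]", "-", x)
  if (x %in% c("+-", "-+", "+/-")) x <- "±"
  aliased <- identical(x, "+")
  if (aliased) x <- "LM"
  list(label = x, aliased = aliased)
}

normalize_topology_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  if (grepl("^peri", x)) return("peri-condensed")
  if (grepl("^angular|^cata", x)) return("angular")
  if (grepl("^linear", x)) return("linear")
  x
}

#' Read a PAH metadata table from delimited text
#'
#' Reads the canonical UTF-8 CSV interchange format (header
#' `id,iupac_name,...`; see [pah_table_columns]). Header matching is case-
#' and spacing-insensitive with built-in synonyms; `column_map` overrides
#' the mapping for non-standard headers. Blank cells become missing. The
#' legacy alias `"+"` for the carcinogenicity label resolves to `"LM"` and
#' is logged in the `alias_log` attribute.
#'
#' The deposited reference file is a spreadsheet; convert it to CSV once for
#' ingestion (no spreadsheet reader is bundled).
#'
#' @param source CSV file path or literal text.
#' @param column_map optional named character vector mapping canonical column
#'   names to the source's header names.
#' @param sep field separator (default `","`).
#' @return a `data.frame` of class `pah_table` in canonical column order,
#'   with attribute `alias_log` (ids whose label was aliased).
#' @export
read_pah_table <- function(source, column_map = NULL, sep = ",") {
  txt <- paste(source_lines(source), collapse = "\n")
  df <- utils::read.table(text = txt, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "", encoding = "UTF-8")
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  hdr <- norm(names(df))
  idx <- integer(0)
  for (col in pah_table_columns) {
    if (!is.null(column_map) && col %in% names(column_map)) {
      j <- which(names(df) == column_map[[col]])
    } else {
      j <- which(hdr %in% .column_synonyms[[col]])
    }
    if (length(j) == 0L) {
      stop(sprintf("missing required column: %s", col), call. = FALSE)
    }
    idx[col] <- j[1L]
  }
  out <- df[, idx, drop = FALSE]
  names(out) <- pah_table_columns
  out$id <- as.character(out$id)
  out$iupac_name <- as.character(out$iupac_name)
  out$xyz_file <- as.character(out$xyz_file)

  for (col in c("n_carbon", "n_hydrogen", "bay", "fjord", "harbor", "canyon")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & nzchar(trimws(as.character(out[[col]]))) &
                 (is.na(v) | v != round(v) | v < 0))
    if (length(bad) > 0L) {
      stop(sprintf("non-integer %s value in row(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out[[col]] <- as.integer(v)
  }
  for (col in c("log_p", "log_iball")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out$topology <- vapply(out$topology, normalize_topology_label, "")
  bad_topo <- which(!is.na(out$topology) &
                    !out$topology %in% c("linear", "angular", "peri-condensed"))
  if (length(bad_topo) > 0L) {
    stop(sprintf("unknown topology label in row(s): %s",
                 paste(bad_topo, collapse = ", ")), call. = FALSE)
  }
  alias_ids <- character(0)
  labels <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    r <- normalize_carc_label(out$carcinogenicity[i])
    labels[i] <- r$label
    if (r$aliased) alias_ids <- c(alias_ids, out$id[i])
  }
  bad_lab <- which(!is.na(labels) & !labels %in% carcinogenicity_levels)
  if (length(bad_lab) > 0L) {
    stop(sprintf("unknown carcinogenicity label '%s' in row(s): %s",
                 labels[bad_lab[1L]], paste(bad_lab, collapse = ", ")), call. = FALSE)
  }
  out$carcinogenicity <- labels
  if (length(alias_ids) > 0L) {
    message(sprintf("carcinogenicity alias '+' -> 'LM' applied to: %s",
                    paste(alias_ids, collapse = ", ")))
  }
  attr(out, "alias_log") <- alias_ids
  class(out) <- c("pah_table", "data.frame")
  out
}

#' Write a PAH metadata table as canonical CSV
#'
#' @param records a `pah_table` data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_pah_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records[, pah_table_columns], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Ordinal encoding of the seven-level carcinogenicity scheme
#'
#' Encodes labels by their position in the stated potency order:
#' `"-"` 0, plus-minus 1, `"L"` 2, `"LM"` 3, `"M"` 4, `"HM"` 5, `"H"` 6.
#' The integer values are a convention of this package; the order is the
#' scheme's. The alias `"+"` resolves to `"LM"` (3). With
#' `collapse_L_to_negative = TRUE`, `"L"` encodes as 0, following the
#' alternative reading in which `"-"` and `"L"` both mean non-carcinogenic.
#'
#' @param label character vector of labels.
#' @param collapse_L_to_negative treat `"L"` as non-carcinogenic.
#' @return integer vector of ordinals (NA for missing labels).
#' @export
encode_carcinogenicity <- function(label, collapse_L_to_negative = FALSE) {
  vapply(label, function(x) {
    lab <- normalize_carc_label(x)$label
    if (is.na(lab)) return(NA_integer_)
    pos <- match(lab, carcinogenicity_levels)
    if (is.na(pos)) stop(sprintf("unknown carcinogenicity label: '%s'", x),
                         call. = FALSE)
    if (collapse_L_to_negative && lab == "L") return(0L)
    pos - 1L
  }, 0L, USE.NAMES = FALSE)
}

#' @rdname encode_carcinogenicity
#' @param code integer ordinal(s) in 0..6.
#' @export
decode_carcinogenicity <- function(code) {
  code <- as.integer(code)
  if (any(!is.na(code) & (code < 0L | code > 6L))) {
    stop("carcinogenicity ordinal must be in 0..6", call. = FALSE)
  }
  carcinogenicity_levels[code + 1L]
}

#' Cross-validate recorded table values against structures
#'
#' For every record whose structure file resolves under `structure_dir`,
#' recomputes carbon/hydrogen counts, BFHC counts and the topology class
#' with [bfhc_compute()] and reports field-by-field mismatches. Recorded
#' values are never modified: discrepancies are findings.
#'
#' @param records a `pah_table`.
#' @param structure_dir directory containing the XYZ / Gaussian-input files
#'   named in `xyz_file`.
#' @param ... passed to [bfhc_compute()] (tolerances, filters, policies).
#' @return An object of class `bfhc_validation`: `n_records`, `n_valid`,
#'   `count_mismatches` (data frame id/field/recorded/recomputed),
#'   `unreadable` (per-record failure messages), `missing_logp`,
#'   `missing_logiball`, `distinct_carcinogenicity_labels`.
#' @export
cross_validate <- function(records, structure_dir, ...) {
  stopifnot(is.data.frame(records))
  fields <- c("n_carbon", "n_hydrogen", "bay", "fjord", "harbor", "canyon", "topology")
  mism <- list()
  unreadable <- character(0)
  n_valid <- 0L
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    path <- file.path(structure_dir, records$xyz_file[i])
    res <- tryCatch(bfhc_compute(path, ...), error = function(e) e)
    if (inherits(res, "error")) {
      unreadable[id] <- conditionMessage(res)
      next
    }
    row_ok <- TRUE
    for (f in fields) {
      rec <- records[[f]][i]
      comp <- res$record[[f]][1L]
      if (!is.na(rec) && !identical(as.character(rec), as.character(comp))) {
        mism[[length(mism) + 1L]] <- data.frame(
          id = id, field = f, recorded = as.character(rec),
          recomputed = as.character(comp), stringsAsFactors = FALSE)
        row_ok <- FALSE
      }
    }
    if (row_ok) n_valid <- n_valid + 1L
  }
  structure(
    list(n_records = nrow(records), n_valid = n_valid,
         count_mismatches = if (length(mism)) do.call(rbind, mism) else
           data.frame(id = character(), field = character(),
                      recorded = character(), recomputed = character()),
         unreadable = unreadable,
         missing_logp = sum(is.na(records$log_p)),
         missing_logiball = sum(is.na(records$log_iball)),
         distinct_carcinogenicity_labels =
           length(unique(stats::na.omit(records$carcinogenicity)))),
    class = "bfhc_validation"
  )
}

#' @export
print.bfhc_validation <- function(x, ...) {
  cat(sprintf("<bfhc_validation> %d records: %d clean, %d mismatched field(s), %d unreadable\n",
              x$n_records, x$n_valid, nrow(x$count_mismatches), length(x$unreadable)))
  if (nrow(x$count_mismatches)) print(x$count_mismatches)
  invisible(x)
}

#' Summarize a PAH metadata table
#'
#' @param records a `pah_table` with at least one row.
#' @return a list: `n_records`, `n_logp` / `n_logiball` (non-missing),
#'   `n_distinct_carcinogenicity_labels`, `topology_tally`,
#'   `carcinogenicity_tally`.
#' @export
summarize_pah_table <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty record list", call. = FALSE)
  list(
    n_records = nrow(records),
    n_logp = sum(!is.na(records$log_p)),
    n_logiball = sum(!is.na(records$log_iball)),
    n_distinct_carcinogenicity_labels =
      length(unique(stats::na.omit(records$carcinogenicity))),
    topology_tally = table(records$topology, useNA = "no"),
    carcinogenicity_tally = table(records$carcinogenicity, useNA = "no")
  )
}
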