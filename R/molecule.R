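# Structure container and XYZ / Gaussian-input readers.

# Elements the parser recognizes; downstream graph construction additionally
# restricts to C/H (the PAH domain).
.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "I"
)

normalize_symbol <- function(x) {
  x <- trimws(x)
  paste0(toupper(substring(x, 1L, 1L)), tolower(substring(x, 2L)))
}

#' Construct a molecule
#'
#' A molecule is an ordered set of atoms: element symbols plus Cartesian
#' coordinates in Angstrom. Symbols are case-normalized (`"c"` becomes `"C"`).
#' Any recognized element is accepted at this stage; graph construction
#' ([perceive_bonds()]) restricts to carbon and hydrogen.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param title free-text comment (source filename or XYZ comment line).
#' @return An object of class `bfhc_molecule` with fields `n`, `symbols`,
#'   `coords`, `title`.
#' @examples
#' m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)), "H2")
#' m$n
#' @export
molecule <- function(symbols, coords, title = "") {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) {
    stop("empty molecule: at least one atom required", call. = FALSE)
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(dim(coords)) || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix", call. = FALSE)
  }
  if (nrow(coords) != length(symbols)) {
    stop(sprintf("symbol/coordinate count mismatch: %d symbols, %d coordinate rows",
                 length(symbols), nrow(coords)), call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite real numbers", call. = FALSE)
  }
  symbols <- normalize_symbol(symbols)
  unknown <- setdiff(unique(symbols), .known_elements)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  dimnames(coords) <- NULL
  structure(
    list(n = length(symbols), symbols = symbols, coords = coords,
         title = as.character(title)[1L]),
    class = "bfhc_molecule"
  )
}

#' @export
print.bfhc_molecule <- function(x, ...) {
  counts <- table(x$symbols)
  formula <- paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
  cat(sprintf("<bfhc_molecule> %s (%d atoms)%s\n", formula, x$n,
              if (nzchar(x$title)) paste0("  \"", x$title, "\"") else ""))
  invisible(x)
}

# Accept a file path or raw text (single string with newlines, or a character
# vector of lines) and return lines with line endings normalized.
source_lines <- function(source) {
  if (is.character(source) && length(source) == 1L &&
      !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    stop("source must be a file path, text, or a connection", call. = FALSE)
  }
  sub("\r$", "", lines)
}

parse_atom_line <- function(line, where) {
  tok <- strsplit(trimws(line), "[[:space:],]+")[[1]]
  if (length(tok) < 4L) {
    stop(sprintf("unparseable atom line (%s): '%s'", where, line), call. = FALSE)
  }
  xyz <- suppressWarnings(as.numeric(tok[2:4]))
  if (anyNA(xyz)) {
    stop(sprintf("unparseable coordinate (%s): '%s'", where, line), call. = FALSE)
  }
  list(symbol = tok[1L], xyz = xyz)
}

#' Read a plain XYZ file
#'
#' Standard XYZ layout: line 1 atom count, line 2 comment, then one
#' `symbol x y z` line per atom (Angstrom). Line-ending convention and
#' surrounding whitespace are irrelevant.
#'
#' @param source file path, text, or connection.
#' @return A [molecule()].
#' @export
read_xyz <- function(source) {
  lines <- source_lines(source)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) < 1L) stop("empty XYZ input", call. = FALSE)
  first <- nonblank[1L]
  count <- suppressWarnings(as.integer(trimws(lines[first])))
  if (is.na(count) || count < 1L) {
    stop(sprintf("malformed atom-count line: '%s'", lines[first]), call. = FALSE)
  }
  title <- if (length(lines) >= first + 1L) trimws(lines[first + 1L]) else ""
  body <- lines[-seq_len(first + 1L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != count) {
    stop(sprintf("atom count mismatch: declared %d, found %d atom lines",
                 count, length(body)), call. = FALSE)
  }
  atoms <- lapply(seq_along(body), function(i) {
    parse_atom_line(body[i], sprintf("atom line %d", i))
  })
  molecule(vapply(atoms, `[[`, "", "symbol"),
           do.call(rbind, lapply(atoms, `[[`, "xyz")),
           title = title)
}

#' Read a Gaussian-input Cartesian block
#'
#' Expects the Gaussian job-file dialect: a route section (lines starting
#' with `#`), a blank line, a title block, a blank line, a
#' charge/multiplicity line (two integers), then `symbol x y z` lines
#' terminated by a blank line or end of file. Route and charge metadata are
#' discarded; only the Cartesian block is returned.
#'
#' @inheritParams read_xyz
#' @return A [molecule()].
#' @export
read_gaussian_input <- function(source) {
  lines <- source_lines(source)
  trimmed <- trimws(lines)
  if (!any(nzchar(trimmed))) stop("no Cartesian block found: empty input", call. = FALSE)
  # charge/multiplicity line: exactly two integers, located after the route.
  is_cm <- grepl("^-?[0-9]+[[:space:]]+-?[0-9]+$", trimmed)
  route <- grep("^#", trimmed)
  cm <- which(is_cm)
  if (length(route) > 0L) cm <- cm[cm > max(route)]
  if (length(cm) == 0L) {
    stop("no Cartesian block found: missing charge/multiplicity line", call. = FALSE)
  }
  cm <- cm[1L]
  title_lines <- trimmed[setdiff(seq_len(cm - 1L),
                                 c(route, which(!nzchar(trimmed))))]
  body <- character()
  for (i in seq(cm + 1L, length.out = max(0L, length(lines) - cm))) {
    if (!nzchar(trimmed[i])) break
    body <- c(body, lines[i])
  }
  if (length(body) == 0L) {
    stop("no Cartesian block found after charge/multiplicity line", call. = FALSE)
  }
  atoms <- lapply(seq_along(body), function(i) {
    parse_atom_line(body[i], sprintf("Cartesian line %d", i))
  })
  molecule(vapply(atoms, `[[`, "", "symbol"),
           do.call(rbind, lapply(atoms, `[[`, "xyz")),
           title = if (length(title_lines)) title_lines[1L] else "")
}

#' Read a structure file with dialect auto-detection
#'
#' If the first non-blank token of the input is an integer the file is
#' treated as plain XYZ, otherwise as a Gaussian input. This matches mixed
#' archives in which both dialects occur.
#'
#' @inheritParams read_xyz
#' @return A [molecule()].
#' @export
read_structure <- function(source) {
  lines <- source_lines(source)
  nonblank <- trimws(lines[nzchar(trimws(lines))])
  if (length(nonblank) == 0L) stop("empty structure input", call. = FALSE)
  first_tok <- strsplit(nonblank[1L], "[[:space:]]+")[[1]][1L]
  if (grepl("^[0-9]+$", first_tok)) read_xyz(lines) else read_gaussian_input(lines)
}

#' Write a molecule as plain XYZ
#'
#' @param mol a [molecule()].
#' @param path destination file path (or connection).
#' @param digits decimal places for coordinates; the default round-trips
#'   through [read_xyz()] to well under 1e-6 Angstrom.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, digits = 8L) {
  stopifnot(inherits(mol, "bfhc_molecule"))
  fmt <- sprintf("%%-2s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6L, digits, digits + 6L, digits, digits + 6L, digits)
  lines <- c(
    as.character(mol$n),
    mol$title,
    vapply(seq_len(mol$n), function(i) {
      sprintf(fmt, mol$symbols[i], mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3])
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}
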