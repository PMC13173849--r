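# End-to-end pipeline: coordinates -> typed graph -> rings -> motifs ->
# topology -> one metadata-table row.

#' Compute BFHC indices and topology for one structure
#'
#' Runs the full chain on a structure file or in-memory molecule: bond
#' perception from covalent-radii thresholds, degree-based typing, minimum
#' cycle basis ring perception, boundary walk, motif detection and
#' fused-ring topology classification.
#'
#' @param x a file path (plain XYZ or Gaussian input, auto-detected), or a
#'   [molecule()].
#' @param id record identifier (defaults to the file base name or the
#'   molecule title).
#' @param radii,tolerance,allow_fragments see [perceive_bonds()].
#' @param max_ring_size see [find_rings()].
#' @param geometry_filter,geometry_max_distance,endpoint_policy see
#'   [detect_motifs()].
#' @param linear_angle_threshold see [classify_topology()].
#' @return An object of class `bfhc_result`: `molecule`, `graph`, `rings`,
#'   `motifs` (a `bfhc_motifs` report), `topology`, and `record` (a one-row
#'   `pah_table` data frame with curated fields left missing).
#' @examples
#' res <- bfhc_compute(canonical("phenanthrene")$molecule)
#' res$motifs$counts[["bay"]]
#' @export
bfhc_compute <- function(x, id = NULL,
                         radii = default_radii, tolerance = 0.40,
                         allow_fragments = FALSE, max_ring_size = 7L,
                         geometry_filter = TRUE, geometry_max_distance = 4.5,
                         endpoint_policy = c("any", "hydrogen-only"),
                         linear_angle_threshold = 170) {
  endpoint_policy <- match.arg(endpoint_policy)
  xyz_file <- NA_character_
  if (inherits(x, "bfhc_molecule")) {
    mol <- x
  } else if (is.character(x) && length(x) == 1L) {
    mol <- read_structure(x)
    xyz_file <- basename(x)
  } else {
    stop("x must be a file path or a bfhc_molecule", call. = FALSE)
  }
  if (is.null(id)) {
    id <- if (!is.na(xyz_file)) sub("\\.[^.]*$", "", xyz_file)
          else if (nzchar(mol$title)) mol$title else "molecule"
  }
  graph <- build_typed_graph(mol, radii = radii, tolerance = tolerance,
                             allow_fragments = allow_fragments)
  rings <- find_rings(graph, max_ring_size = max_ring_size)
  motifs <- detect_motifs(rings, graph, geometry_filter = geometry_filter,
                          geometry_max_distance = geometry_max_distance,
                          endpoint_policy = endpoint_policy)
  topology <- classify_topology(rings, graph,
                                linear_angle_threshold = linear_angle_threshold)
  record <- data.frame(
    id = id,
    iupac_name = if (nzchar(mol$title)) mol$title else NA_character_,
    xyz_file = xyz_file,
    n_carbon = sum(mol$symbols == "C"),
    n_hydrogen = sum(mol$symbols == "H"),
    bay = unname(motifs$counts[["bay"]]),
    fjord = unname(motifs$counts[["fjord"]]),
    harbor = unname(motifs$counts[["harbor"]]),
    canyon = unname(motifs$counts[["canyon"]]),
    topology = topology,
    carcinogenicity = NA_character_,
    log_p = NA_real_,
    log_iball = NA_real_,
    stringsAsFactors = FALSE
  )
  class(record) <- c("pah_table", "data.frame")
  structure(list(molecule = mol, graph = graph, rings = rings,
                 motifs = motifs, topology = topology, record = record),
            class = "bfhc_result")
}

#' @export
print.bfhc_result <- function(x, ...) {
  r <- x$record
  cat(sprintf("<bfhc_result> %s: C%dH%d  B=%d F=%d H=%d C=%d  %s\n",
              r$id, r$n_carbon, r$n_hydrogen, r$bay, r$fjord, r$harbor,
              r$canyon, r$topology))
  invisible(x)
}

#' Compute a metadata table for a set of structure files
#'
#' @param paths character vector of structure file paths.
#' @param ... passed to [bfhc_compute()].
#' @return a `pah_table` data frame, one row per file.
#' @export
bfhc_compute_files <- function(paths, ...) {
  if (length(paths) == 0L) stop("no structure files given", call. = FALSE)
  rows <- lapply(paths, function(p) bfhc_compute(p, ...)$record)
  out <- do.call(rbind, rows)
  class(out) <- c("pah_table", "data.frame")
  out
}
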