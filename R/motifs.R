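# Bay / Fjord / Harbor / Canyon motif detection on the boundary walk, an
# independent brute-force oracle, and report serialization.

.motif_kinds <- c("fissure", "bay", "fjord", "harbor", "canyon", "extended")

# run length k (consecutive junction carbons) -> motif kind
run_kind <- function(k) {
  if (k >= 6L) "extended" else .motif_kinds[k]
}

new_motif_report <- function(motifs, n_boundary_junction) {
  counts <- vapply(.motif_kinds, function(kind) {
    sum(vapply(motifs, function(m) m$kind == kind && m$passed_geometry, TRUE))
  }, 0L)
  structure(
    list(counts = counts, motifs = motifs,
         n_boundary_junction = as.integer(n_boundary_junction)),
    class = "bfhc_motifs"
  )
}

make_motif <- function(kind, path, graph, geometry_filter, geometry_max_distance) {
  l <- path[1L]
  r <- path[length(path)]
  bonded <- graph$adjacency[l, r]
  d <- graph$distance_matrix[l, r]
  passed <- !bonded && (!geometry_filter || d <= geometry_max_distance)
  list(kind = kind, path = path,
       endpoint_types = graph$atom_type[c(l, r)],
       endpoint_distance = d, passed_geometry = passed)
}

#' Detect Bay, Fjord, Harbor and Canyon regions
#'
#' Scans the cyclic boundary walk for maximal runs of consecutive junction
#' carbons (ring membership >= 2) flanked on both sides by rim carbons
#' (membership 1). A run of length k yields: k = 1 a fissure (reported but
#' not a BFHC index), k = 2 a Bay (4-atom path `X-C-C-Y`), k = 3 a Fjord
#' (5-atom path), k = 4 a Harbor (6 atoms), k = 5 a Canyon (7 atoms),
#' k >= 6 an extended region (warning). The motif path is the left flank,
#' the run, then the right flank, in walk order.
#'
#' Flank ("endpoint") atoms X and Y are typically hydrogen-bearing sp2
#' carbons; under `endpoint_policy = "any"` (default) substituent-bearing
#' flanks also qualify, under `"hydrogen-only"` both flanks must carry a
#' hydrogen (non-qualifying motifs are dropped). The geometry filter
#' (default on) additionally requires the through-space X...Y distance to be
#' at most `geometry_max_distance`; motifs failing it are retained with
#' `passed_geometry = FALSE` and excluded from the counts. Runs whose flanks
#' are bonded to each other (possible only in non-hexagonal rings) violate
#' the motif definition and are dropped.
#'
#' @param rings a `bfhc_rings` from [find_rings()].
#' @param graph the matching typed `bfhc_graph`.
#' @param geometry_filter logical; apply the endpoint-distance validity
#'   filter.
#' @param geometry_max_distance maximum X...Y distance in Angstrom
#'   (default 4.5).
#' @param endpoint_policy `"any"` or `"hydrogen-only"`.
#' @return An object of class `bfhc_motifs`: `counts` (named integer vector
#'   over fissure/bay/fjord/harbor/canyon/extended), `motifs` (list with
#'   `kind`, `path` of 1-based atom indices, `endpoint_types`,
#'   `endpoint_distance`, `passed_geometry`), and `n_boundary_junction`.
#' @export
detect_motifs <- function(rings, graph, geometry_filter = TRUE,
                          geometry_max_distance = 4.5,
                          endpoint_policy = c("any", "hydrogen-only")) {
  endpoint_policy <- match.arg(endpoint_policy)
  bw <- boundary_walk(rings, graph)
  f <- bw$is_junction
  L <- length(f)
  n_junction <- sum(f)
  if (!any(f)) return(new_motif_report(list(), 0L))
  if (all(f)) {
    stop("boundary consists entirely of junction carbons; no flanked runs exist",
         call. = FALSE)
  }
  # rotate the cyclic walk so it starts on a rim (non-junction) carbon;
  # every junction run is then internal to the rotated vector
  s <- which(!f)[1L]
  ord <- ((s - 1L + seq_len(L) - 1L) %% L) + 1L
  fr <- f[ord]
  wr <- bw$walk[ord]
  runs <- rle(fr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  motifs <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    k <- runs$lengths[i]
    left <- wr[starts[i] - 1L]                    # rotated start is a rim atom
    right <- wr[if (ends[i] == L) 1L else ends[i] + 1L]
    path <- c(left, wr[starts[i]:ends[i]], right)
    kind <- run_kind(k)
    if (kind == "extended") {
      warning(sprintf("extended junction run of length %d (not a BFHC index)", k),
              call. = FALSE)
    }
    if (endpoint_policy == "hydrogen-only" &&
        !(graph$has_hydrogen[left] && graph$has_hydrogen[right])) {
      next
    }
    m <- make_motif(kind, path, graph, geometry_filter, geometry_max_distance)
    if (graph$adjacency[path[1L], path[length(path)]]) next  # bonded flanks: not a motif
    motifs[[length(motifs) + 1L]] <- m
  }
  new_motif_report(motifs, n_junction)
}

#' Brute-force motif oracle
#'
#' Independent reference implementation used for testing [detect_motifs()]:
#' enumerates all simple paths of 3 to 7 atoms over the boundary-edge
#' subgraph (edges belonging to exactly one ring) whose interior atoms are
#' all boundary junction carbons, whose endpoints are membership-1 boundary
#' carbons not bonded to each other, deduplicating path reversals. Shares no
#' code with the run-length detector: paths come from
#' [igraph::all_simple_paths()] rather than an ordered walk. Pure topology
#' (no geometry filter).
#'
#' @inheritParams detect_motifs
#' @return a `bfhc_motifs` report.
#' @export
brute_force_motifs <- function(rings, graph) {
  stopifnot(inherits(rings, "bfhc_rings"), inherits(graph, "bfhc_graph"))
  erc <- rings$edge_ring_count
  bnd <- erc == 1L
  bverts <- which(rowSums(bnd) > 0L)
  if (length(bverts) == 0L) stop("no boundary edges", call. = FALSE)
  rim <- bverts[rings$membership[bverts] == 1L]
  junction <- bverts[rings$membership[bverts] >= 2L]
  if (length(junction) == 0L) return(new_motif_report(list(), 0L))

  g <- igraph::graph_from_adjacency_matrix(bnd[bverts, bverts, drop = FALSE],
                                           mode = "undirected")
  igraph::V(g)$name <- as.character(bverts)
  seen <- character()
  motifs <- list()
  for (e in rim) {
    others <- setdiff(rim, e)
    if (length(others) == 0L) next
    paths <- igraph::all_simple_paths(g, from = as.character(e),
                                      to = as.character(others), cutoff = 6L)
    for (p in paths) {
      atoms <- as.integer(names(p))
      len <- length(atoms)
      if (len < 3L || len > 7L) next
      interior <- atoms[-c(1L, len)]
      if (!all(interior %in% junction)) next
      if (graph$adjacency[atoms[1L], atoms[len]]) next
      key <- paste(min(atoms[1L], atoms[len]), max(atoms[1L], atoms[len]),
                   paste(sort(interior), collapse = "."), sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      motifs[[length(motifs) + 1L]] <-
        make_motif(run_kind(len - 2L), atoms, graph,
                   geometry_filter = FALSE, geometry_max_distance = Inf)
    }
  }
  new_motif_report(motifs, length(junction))
}

#' @export
print.bfhc_motifs <- function(x, ...) {
  cat("<bfhc_motifs> ",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Serialize a motif report
#'
#' Deterministic serialization of a motif report. Paths are listed with
#' 0-based atom indices in input-file order (the in-memory representation is
#' 1-based R indexing).
#'
#' @param report a `bfhc_motifs` report.
#' @param format `"table"` (aligned text) or `"json"`.
#' @return a character scalar (`"json"`) or vector of lines (`"table"`).
#' @export
report_motifs <- function(report, format = c("table", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "bfhc_motifs"))
  rows <- lapply(report$motifs, function(m) {
    data.frame(kind = m$kind,
               path_indices = paste(m$path - 1L, collapse = "-"),
               endpoint_distance = round(m$endpoint_distance, 4),
               passed_geometry = m$passed_geometry,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), path_indices = character(),
               endpoint_distance = numeric(), passed_geometry = logical())
  if (format == "table") {
    header <- paste(c("kind", "path_indices", "endpoint_distance", "passed_geometry"),
                    collapse = "\t")
    body <- if (nrow(df)) apply(df, 1L, function(r) paste(r, collapse = "\t")) else character()
    return(c(header, unname(body)))
  }
  jsonlite::toJSON(
    list(counts = as.list(report$counts),
         n_boundary_junction = report$n_boundary_junction,
         motifs = lapply(report$motifs, function(m) {
           list(kind = m$kind, path = m$path - 1L,
                endpoint_types = m$endpoint_types,
                endpoint_distance = m$endpoint_distance,
                passed_geometry = m$passed_geometry)
         })),
    auto_unbox = TRUE, digits = NA
  )
}

#' Rebuild a motif report from its JSON serialization
#'
#' Inverse of `report_motifs(report, "json")`; used to verify round-tripping.
#'
#' @param json a JSON string produced by [report_motifs()].
#' @return a `bfhc_motifs` report.
#' @export
motif_report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  motifs <- lapply(x$motifs, function(m) {
    list(kind = m$kind,
         path = vapply(m$path, as.integer, 0L) + 1L,
         endpoint_types = vapply(m$endpoint_types, as.character, ""),
         endpoint_distance = as.numeric(m$endpoint_distance),
         passed_geometry = isTRUE(m$passed_geometry))
  })
  new_motif_report(motifs, as.integer(x$n_boundary_junction))
}
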