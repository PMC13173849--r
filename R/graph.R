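# Bond perception from covalent-radii thresholds and degree-based atom typing.

#' Default covalent radii (Angstrom)
#'
#' Standard single-bond covalent radii for carbon and hydrogen. With the
#' default tolerance of 0.40 Angstrom these accept aromatic C-C (~1.40 A) and
#' C-H (~1.09 A) with wide margin while rejecting non-bonded contacts
#' (> 2.4 A).
#' @export
default_radii <- c(C = 0.76, H = 0.31)

#' Pairwise Euclidean distance matrix
#'
#' @param mol a [molecule()] with at least two atoms.
#' @return symmetric n x n matrix of distances in Angstrom, zero diagonal.
#' @export
compute_distance_matrix <- function(mol) {
  stopifnot(inherits(mol, "bfhc_molecule"))
  if (mol$n < 2L) stop("distance matrix requires at least 2 atoms", call. = FALSE)
  unname(as.matrix(stats::dist(mol$coords)))
}

#' Perceive bonds from interatomic distances
#'
#' Atoms i and j are bonded iff `0 < d(i,j) <= r(i) + r(j) + tolerance`.
#' H-H bonds are forbidden regardless of distance: in crowded fjord/canyon
#' geometries opposing hydrogens can approach ~1.9 A and must not be
#' mis-bonded. The perceived graph is validated against PAH chemistry:
#' every hydrogen must have degree exactly 1 with a carbon neighbor, and
#' every carbon degree 2, 3 or 4. Only C/H molecules are accepted.
#'
#' @param mol a [molecule()] containing only C and H.
#' @param radii named numeric vector of per-element covalent radii (Angstrom).
#' @param tolerance bond threshold slack in Angstrom.
#' @param allow_fragments if `FALSE` (default) a disconnected carbon skeleton
#'   is an error; if `TRUE` it is kept and downstream analyses work per fused
#'   component.
#' @return An object of class `bfhc_graph`: the molecule plus
#'   `distance_matrix`, `adjacency` (logical, symmetric, false diagonal),
#'   `degree`, and (after [assign_atom_types()]) `atom_type`/`has_hydrogen`.
#' @export
perceive_bonds <- function(mol, radii = default_radii,
                           tolerance = 0.40, allow_fragments = FALSE) {
  stopifnot(inherits(mol, "bfhc_molecule"))
  non_ch <- setdiff(unique(mol$symbols), c("C", "H"))
  if (length(non_ch) > 0L) {
    stop(sprintf("graph construction supports C/H molecules only; found: %s",
                 paste(non_ch, collapse = ", ")), call. = FALSE)
  }
  missing_r <- setdiff(unique(mol$symbols), names(radii))
  if (length(missing_r) > 0L) {
    stop(sprintf("no covalent radius for element(s): %s",
                 paste(missing_r, collapse = ", ")), call. = FALSE)
  }
  d <- compute_distance_matrix(mol)
  r <- radii[mol$symbols]
  thresh <- outer(r, r, `+`) + tolerance
  adj <- d > 0 & d <= thresh
  is_h <- mol$symbols == "H"
  adj[is_h, is_h] <- FALSE          # chemistry guard: no H-H bonds
  diag(adj) <- FALSE
  dimnames(adj) <- NULL
  deg <- rowSums(adj)

  bad_h <- which(is_h & deg != 1L)
  if (length(bad_h) > 0L) {
    stop(sprintf("hydrogen atom(s) with degree != 1: %s (degrees %s)",
                 paste(bad_h, collapse = ", "),
                 paste(deg[bad_h], collapse = ", ")), call. = FALSE)
  }
  h_to_c <- vapply(which(is_h), function(i) mol$symbols[which(adj[i, ])] == "C", TRUE)
  if (!all(h_to_c)) {
    stop("hydrogen bonded to a non-carbon atom", call. = FALSE)
  }
  is_c <- !is_h
  bad_c <- which(is_c & !(deg %in% 2:4))
  if (length(bad_c) > 0L) {
    stop(sprintf("carbon atom(s) with degree outside {2,3,4}: %s (degrees %s)",
                 paste(bad_c, collapse = ", "),
                 paste(deg[bad_c], collapse = ", ")), call. = FALSE)
  }

  carbons <- which(is_c)
  g <- igraph::graph_from_adjacency_matrix(adj[carbons, carbons, drop = FALSE],
                                           mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L && !allow_fragments) {
    stop(sprintf(paste0("disconnected carbon skeleton (%d fragments); ",
                        "set allow_fragments = TRUE for per-fragment processing"),
                 comp$no), call. = FALSE)
  }

  structure(
    list(molecule = mol, distance_matrix = d, adjacency = adj,
         degree = as.integer(deg), is_carbon = is_c,
         carbon_fragments = split(carbons, comp$membership),
         atom_type = NULL, has_hydrogen = NULL),
    class = "bfhc_graph"
  )
}

#' Assign degree-based atom types
#'
#' Hydrogen atoms are labeled `H`. Carbons are labeled from their graph
#' degree: 2 -> `sp`, 3 -> `sp2` (or `sp2-H` when at least one neighbor is a
#' hydrogen), 4 -> `sp3`. `has_hydrogen` flags each carbon bearing at least
#' one hydrogen; this feeds the motif endpoint policy.
#'
#' @param graph a `bfhc_graph` from [perceive_bonds()].
#' @return the graph with `atom_type` and `has_hydrogen` populated.
#' @export
assign_atom_types <- function(graph) {
  stopifnot(inherits(graph, "bfhc_graph"))
  sym <- graph$molecule$symbols
  n <- graph$molecule$n
  has_h <- vapply(seq_len(n), function(i) {
    any(sym[which(graph$adjacency[i, ])] == "H")
  }, TRUE)
  type <- character(n)
  for (i in seq_len(n)) {
    if (sym[i] == "H") {
      type[i] <- "H"
    } else {
      type[i] <- switch(as.character(graph$degree[i]),
                        "2" = "sp",
                        "3" = if (has_h[i]) "sp2-H" else "sp2",
                        "4" = "sp3",
                        stop(sprintf("atom %d: unexpected carbon degree %d",
                                     i, graph$degree[i]), call. = FALSE))
    }
  }
  graph$atom_type <- type
  graph$has_hydrogen <- has_h & graph$is_carbon
  graph
}

#' Build a fully typed molecular graph in one call
#'
#' Convenience wrapper: [perceive_bonds()] followed by [assign_atom_types()].
#'
#' @inheritParams perceive_bonds
#' @return a typed `bfhc_graph`.
#' @export
build_typed_graph <- function(mol, radii = default_radii,
                              tolerance = 0.40, allow_fragments = FALSE) {
  assign_atom_types(perceive_bonds(mol, radii = radii, tolerance = tolerance,
                                   allow_fragments = allow_fragments))
}

#' @export
print.bfhc_graph <- function(x, ...) {
  nb <- sum(x$adjacency) / 2
  cat(sprintf("<bfhc_graph> %d atoms, %d bonds%s\n", x$molecule$n, nb,
              if (!is.null(x$atom_type)) " (typed)" else ""))
  invisible(x)
}
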