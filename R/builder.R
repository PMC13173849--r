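# Idealized benzenoid geometry builder: hexagonal-lattice fusion specs,
# helicene spirals, a canonical fixture library, and a random polyhex
# generator. Emits ground-truth connectivity alongside coordinates so that
# bond perception can be tested against it rather than assumed.

# axial-lattice neighbor directions, in cyclic order around a cell
# (center angles 0, 60, ..., 300 degrees)
.hex_dirs <- rbind(c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1))

hex_adjacent <- function(a, b) {
  d <- c(a[1] - b[1], a[2] - b[2])
  any(.hex_dirs[, 1] == d[1] & .hex_dirs[, 2] == d[2])
}

hex_center <- function(q, r, cc) {
  c(sqrt(3) * cc * (q + r / 2), 1.5 * cc * r)
}

#' Hexagon-fusion specification
#'
#' Describes a benzenoid as a set of hexagonal cells on the axial lattice
#' plus the pairs of cells that are actually fused. By default every
#' lattice-adjacent pair is fused (ordinary polyhex benzenoids); helicenes
#' restrict fusion to consecutive cells and use a per-cell z rise so that
#' lattice-overlapping terminal rings do not collide.
#'
#' @param cells integer matrix (n x 2) of axial coordinates `(q, r)`.
#' @param fusion_edges integer matrix (m x 2) of fused cell-index pairs, or
#'   `NULL` for all lattice-adjacent pairs.
#' @param z_rise out-of-plane rise per cell in Angstrom (0 = planar).
#' @param name optional label.
#' @return an object of class `bfhc_hexspec`.
#' @export
hex_spec <- function(cells, fusion_edges = NULL, z_rise = 0, name = "") {
  cells <- matrix(as.integer(cells), ncol = 2L)
  nc <- nrow(cells)
  if (anyDuplicated(split(cells, row(cells)))) stop("duplicate cells", call. = FALSE)
  adj_pairs <- NULL
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) {
      for (j in seq(i + 1L, nc)) {
        if (hex_adjacent(cells[i, ], cells[j, ])) adj_pairs <- rbind(adj_pairs, c(i, j))
      }
    }
  }
  if (is.null(fusion_edges)) {
    fusion_edges <- if (is.null(adj_pairs)) matrix(integer(), ncol = 2L) else adj_pairs
  } else {
    fusion_edges <- matrix(as.integer(fusion_edges), ncol = 2L)
    fusion_edges <- t(apply(fusion_edges, 1L, sort))
    ok <- apply(fusion_edges, 1L, function(e) {
      !is.null(adj_pairs) && any(adj_pairs[, 1] == e[1] & adj_pairs[, 2] == e[2])
    })
    if (!all(ok)) stop("fusion_edges must connect lattice-adjacent cells", call. = FALSE)
  }
  if (nc > 1L) {
    g <- igraph::graph_from_edgelist(fusion_edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nc - igraph::vcount(g)))
    if (igraph::components(g)$no != 1L) {
      stop("fusion graph over cells must be connected", call. = FALSE)
    }
  }
  structure(list(cells = cells, fusion_edges = fusion_edges,
                 z_rise = as.numeric(z_rise), name = name),
            class = "bfhc_hexspec")
}

#' Build an idealized benzenoid geometry from a hexagon spec
#'
#' Carbons are placed at the union of hexagon vertices; vertices at the same
#' lattice position are merged only between cells connected through fusion
#' edges (so spiral specs keep non-fused lattice-coincident rings apart,
#' with the atom z taken as the mean of the contributing cells' z offsets).
#' A hydrogen is added along the external bisector to every carbon with
#' fewer than three carbon neighbors. The exact intended adjacency is
#' emitted alongside the coordinates: fixtures test bond perception, they do
#' not assume it.
#'
#' @param spec a [hex_spec()].
#' @param cc_bond aromatic C-C bond length in Angstrom (default 1.40).
#' @param ch_bond C-H bond length in Angstrom (default 1.09).
#' @return A list of class `bfhc_built`: `molecule` (carbons first, then
#'   hydrogens), `adjacency` (ground-truth logical bond matrix), `spec`.
#' @export
build_benzenoid <- function(spec, cc_bond = 1.40, ch_bond = 1.09) {
  stopifnot(inherits(spec, "bfhc_hexspec"))
  nc <- nrow(spec$cells)
  zs <- (seq_len(nc) - 1L) * spec$z_rise

  # vertex instances: one per (cell, corner)
  key <- character(0); cell_of <- integer(0); pos <- NULL
  for (i in seq_len(nc)) {
    ctr <- hex_center(spec$cells[i, 1], spec$cells[i, 2], cc_bond)
    for (k in 0:5) {
      a <- pi / 2 + k * pi / 3
      p <- ctr + cc_bond * c(cos(a), sin(a))
      # integer-scaled key: immune to the "-0.0000" formatting pitfall
      key <- c(key, paste(as.integer(round(p[1] * 1e4)),
                          as.integer(round(p[2] * 1e4)), sep = "_"))
      cell_of <- c(cell_of, i)
      pos <- rbind(pos, p)
    }
  }
  fused <- matrix(FALSE, nc, nc)
  if (nrow(spec$fusion_edges) > 0L) {
    fused[spec$fusion_edges] <- TRUE
    fused[spec$fusion_edges[, c(2, 1), drop = FALSE]] <- TRUE
  }

  # merge coincident vertices per fusion-connected cluster of cells
  atom_of_instance <- integer(length(key))
  coords <- NULL
  groups <- split(seq_along(key), key)
  for (g in groups) {
    cells_g <- cell_of[g]
    comp <- seq_along(g)                    # union-find over <= 3 cells
    for (a in seq_along(g)) {
      for (b in seq_along(g)) {
        if (fused[cells_g[a], cells_g[b]]) {
          comp[comp == comp[b]] <- comp[a]
        }
      }
    }
    for (cid in unique(comp)) {
      members <- g[comp == cid]
      z <- mean(zs[cell_of[members]])
      coords <- rbind(coords, c(pos[members[1L], ], z))
      atom_of_instance[members] <- nrow(coords)
    }
    if (spec$z_rise == 0 && length(unique(comp)) > 1L) {
      stop("planar policy requested for a self-overlapping spec; use a spiral z_rise",
           call. = FALSE)
    }
  }
  n_c <- nrow(coords)
  # deterministic carbon order
  ord <- order(round(coords[, 1], 4), round(coords[, 2], 4), round(coords[, 3], 4))
  rank <- match(seq_len(n_c), ord)
  coords <- coords[ord, , drop = FALSE]
  atom_of_instance <- rank[atom_of_instance]

  cc_adj <- matrix(FALSE, n_c, n_c)
  for (i in seq_len(nc)) {
    inst <- (i - 1L) * 6L + 1:6
    at <- atom_of_instance[inst]
    for (k in 1:6) {
      a <- at[k]; b <- at[if (k == 6L) 1L else k + 1L]
      cc_adj[a, b] <- cc_adj[b, a] <- TRUE
    }
  }

  # hydrogens on rim carbons, along the external bisector
  h_coords <- NULL; h_anchor <- integer(0)
  for (a in seq_len(n_c)) {
    nb <- which(cc_adj[a, ])
    if (length(nb) >= 3L) next
    dirs <- vapply(nb, function(b) {
      v <- coords[b, ] - coords[a, ]
      v / sqrt(sum(v^2))
    }, numeric(3))
    s <- -rowSums(dirs)
    s <- s / sqrt(sum(s^2))
    h_coords <- rbind(h_coords, coords[a, ] + ch_bond * s)
    h_anchor <- c(h_anchor, a)
  }
  n_h <- length(h_anchor)
  n <- n_c + n_h
  adj <- matrix(FALSE, n, n)
  adj[seq_len(n_c), seq_len(n_c)] <- cc_adj
  for (j in seq_len(n_h)) {
    adj[h_anchor[j], n_c + j] <- adj[n_c + j, h_anchor[j]] <- TRUE
  }
  mol <- molecule(c(rep("C", n_c), rep("H", n_h)),
                  rbind(coords, h_coords), title = spec$name)
  structure(list(molecule = mol, adjacency = adj, spec = spec),
            class = "bfhc_built")
}

#' Attach a methyl group to a built fixture
#'
#' Replaces the hydrogen on the given carbon with an sp3 carbon bearing
#' three hydrogens (tetrahedral H-C-C angles). Used to exercise the motif
#' endpoint policy on substituted rim positions.
#'
#' @param built a `bfhc_built` from [build_benzenoid()].
#' @param at 1-based index of a hydrogen-bearing carbon.
#' @param cc_single C(sp2)-C(sp3) bond length (default 1.50 Angstrom).
#' @param ch_bond methyl C-H bond length (default 1.09 Angstrom).
#' @return a `bfhc_built` with updated molecule and ground-truth adjacency.
#' @export
methylate <- function(built, at, cc_single = 1.50, ch_bond = 1.09) {
  stopifnot(inherits(built, "bfhc_built"))
  mol <- built$molecule
  adj <- built$adjacency
  if (mol$symbols[at] != "C") stop("attachment site must be a carbon", call. = FALSE)
  h <- which(adj[at, ] & mol$symbols == "H")
  if (length(h) != 1L) stop("attachment carbon must bear exactly one hydrogen", call. = FALSE)
  u <- mol$coords[h, ] - mol$coords[at, ]
  u <- u / sqrt(sum(u^2))
  cm <- mol$coords[at, ] + cc_single * u
  # orthonormal frame perpendicular to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
  hpos <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(th) {
    d <- (1 / 3) * u + sqrt(8) / 3 * (cos(th) * v + sin(th) * w)
    cm + ch_bond * d
  }, numeric(3)))

  keep <- setdiff(seq_len(mol$n), h)
  sym <- c(mol$symbols[keep], "C", rep("H", 3L))
  crd <- rbind(mol$coords[keep, , drop = FALSE], cm, hpos)
  n <- length(sym)
  new_adj <- matrix(FALSE, n, n)
  new_adj[seq_along(keep), seq_along(keep)] <- adj[keep, keep]
  at_new <- match(at, keep)
  icm <- length(keep) + 1L
  new_adj[at_new, icm] <- new_adj[icm, at_new] <- TRUE
  for (j in 1:3) {
    new_adj[icm, icm + j] <- new_adj[icm + j, icm] <- TRUE
  }
  structure(list(molecule = molecule(sym, crd, title = mol$title),
                 adjacency = new_adj, spec = built$spec),
            class = "bfhc_built")
}

.canonical_specs <- function() {
  row_cells <- function(n) cbind(seq_len(n) - 1L, 0L)
  helicene <- function(n) {
    hex_spec(.hex_dirs[seq_len(n), , drop = FALSE],
             fusion_edges = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
             z_rise = 0.8)
  }
  list(
    "benzene"               = hex_spec(cbind(0L, 0L)),
    "naphthalene"           = hex_spec(row_cells(2)),
    "anthracene"            = hex_spec(row_cells(3)),
    "tetracene"             = hex_spec(row_cells(4)),
    "pentacene"             = hex_spec(row_cells(5)),
    "phenanthrene"          = hex_spec(rbind(c(0, 0), c(1, 0), c(1, 1))),
    "chrysene"              = hex_spec(rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1))),
    "benzo[c]phenanthrene"  = helicene(4),
    "triphenylene"          = hex_spec(rbind(c(0, 0), c(1, 0), c(-1, 1), c(0, -1))),
    "pyrene"                = hex_spec(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))),
    "benzo[a]pyrene"        = hex_spec(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 1))),
    "perylene"              = hex_spec(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))),
    "coronene"              = hex_spec(rbind(c(0, 0), .hex_dirs)),
    "pentahelicene"         = helicene(5),
    "hexahelicene"          = helicene(6)
  )
}

#' Canonical fixture library
#'
#' Deterministic idealized geometries for fifteen reference PAHs, from
#' benzene through the acene, angular, peri-condensed and helicene series.
#'
#' @param name compound name; see [canonical_names()].
#' @return a `bfhc_built` (molecule + ground-truth adjacency).
#' @export
canonical <- function(name) {
  specs <- .canonical_specs()
  if (!name %in% names(specs)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(specs), collapse = ", ")), call. = FALSE)
  }
  spec <- specs[[name]]
  spec$name <- name
  build_benzenoid(spec)
}

#' @rdname canonical
#' @export
canonical_names <- function() names(.canonical_specs())

# TRUE when adding the candidate cell leaves no enclosed empty lattice cell
# (coronoid holes have two boundary cycles and are out of scope).
no_hole <- function(cells) {
  qr <- range(cells[, 1]); rr <- range(cells[, 2])
  qs <- (qr[1] - 1L):(qr[2] + 1L); rs <- (rr[1] - 1L):(rr[2] + 1L)
  grid <- expand.grid(q = qs, r = rs)
  keyc <- paste(cells[, 1], cells[, 2])
  keyg <- paste(grid$q, grid$r)
  empty <- !(keyg %in% keyc)
  border <- grid$q %in% range(qs) | grid$r %in% range(rs)
  reach <- empty & border
  repeat {
    grew <- FALSE
    for (i in which(empty & !reach)) {
      for (d in seq_len(6)) {
        j <- which(grid$q == grid$q[i] + .hex_dirs[d, 1] &
                   grid$r == grid$r[i] + .hex_dirs[d, 2])
        if (length(j) == 1L && reach[j]) { reach[i] <- TRUE; grew <- TRUE; break }
      }
    }
    if (!grew) break
  }
  all(reach[empty])
}

# TRUE when no pair of occupied cells sits in a "meta" arrangement with both
# of its common neighbor cells empty. On the planar lattice such a pair's
# rim vertices coincide to within one bond length (the cove-closing pattern
# of [5]helicene and beyond), so the spec is not representable as a planar
# molecule; helicene fixtures use the spiral policy instead.
no_meta_clash <- function(cells) {
  key <- paste(cells[, 1], cells[, 2])
  n <- nrow(cells)
  for (i in seq_len(n)) {
    for (k in 1:6) {
      d1 <- .hex_dirs[k, ]
      d2 <- .hex_dirs[if (k == 6L) 1L else k + 1L, ]
      other <- cells[i, ] + d1 + d2
      if (!paste(other[1], other[2]) %in% key) next
      c1 <- cells[i, ] + d1
      c2 <- cells[i, ] + d2
      if (!paste(c1[1], c1[2]) %in% key && !paste(c2[1], c2[2]) %in% key) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Random connected polyhex specification
#'
#' Grows a connected polyhex by repeated uniform cell addition on the
#' frontier, rejecting additions that would enclose a hole or create a
#' cove-closing contact (two rings one bond apart across an empty cell,
#' which a planar lattice cannot realize without collision). Reproducible
#' for a given seed; the caller's RNG state is left untouched.
#'
#' @param n_cells number of hexagons, between 1 and 10.
#' @param seed integer seed.
#' @return a planar [hex_spec()] with all lattice-adjacent pairs fused.
#' @export
random_polyhex <- function(n_cells, seed) {
  if (n_cells < 1L || n_cells > 10L) stop("n_cells must be in [1, 10]", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  cells <- matrix(c(0L, 0L), ncol = 2L)
  while (nrow(cells) < n_cells) {
    frontier <- unique(do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sweep(.hex_dirs, 2L, -cells[i, ])
    })))
    keyc <- paste(cells[, 1], cells[, 2])
    frontier <- frontier[!(paste(frontier[, 1], frontier[, 2]) %in% keyc), , drop = FALSE]
    ok <- vapply(seq_len(nrow(frontier)), function(i) {
      cand <- rbind(cells, frontier[i, ])
      no_meta_clash(cand) && no_hole(cand)
    }, TRUE)
    frontier <- frontier[ok, , drop = FALSE]
    pick <- frontier[sample.int(nrow(frontier), 1L), ]
    cells <- rbind(cells, pick)
  }
  hex_spec(cells, name = sprintf("polyhex_%d_seed%d", n_cells, seed))
}
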