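# Ring perception (minimum cycle basis), boundary walk, and fused-ring
# topology classification.

# Deterministic BFS trees from every root over an adjacency list.
# Neighbors are visited in ascending index order, so shortest paths (and
# hence the Horton candidate set) are reproducible across platforms.
bfs_all <- function(nbr) {
  n <- length(nbr)
  dist <- matrix(NA_integer_, n, n)
  parent <- matrix(NA_integer_, n, n)
  for (root in seq_len(n)) {
    d <- rep(NA_integer_, n)
    p <- rep(NA_integer_, n)
    d[root] <- 0L
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in nbr[[v]]) {
        if (is.na(d[w])) {
          d[w] <- d[v] + 1L
          p[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    dist[root, ] <- d
    parent[root, ] <- p
  }
  list(dist = dist, parent = parent)
}

bfs_path <- function(parent, root, v) {
  path <- v
  while (v != root) {
    v <- parent[root, v]
    path <- c(v, path)
  }
  path
}

# Horton's minimum cycle basis over a connected simple graph given as a
# logical adjacency matrix (local vertex indices). Returns a list of cycles,
# each an ordered vertex vector. Candidate cycles C(v, e) are formed from
# shortest paths v..x and v..y plus edge e = (x, y); a greedy GF(2)
# elimination over the edge space picks |E| - |V| + 1 independent shortest
# candidates. For planar fused benzenoids this basis is the set of faces.
minimum_cycle_basis <- function(adj) {
  n <- nrow(adj)
  ends <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  m <- nrow(ends)
  rank_target <- m - n + 1L
  if (rank_target <= 0L) return(list())
  eid <- matrix(0L, n, n)
  for (k in seq_len(m)) {
    eid[ends[k, 1L], ends[k, 2L]] <- k
    eid[ends[k, 2L], ends[k, 1L]] <- k
  }
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ]))
  bfs <- bfs_all(nbr)

  cand <- new.env(parent = emptyenv())
  for (v in seq_len(n)) {
    for (k in seq_len(m)) {
      x <- ends[k, 1L]; y <- ends[k, 2L]
      if (v == x || v == y) next
      px <- bfs_path(bfs$parent, v, x)
      py <- bfs_path(bfs$parent, v, y)
      if (length(intersect(px, py)) != 1L) next   # paths must share only v
      verts <- c(px, rev(py)[-length(py)])
      len <- length(verts)
      eids <- integer(len)
      ok <- TRUE
      for (i in seq_len(len)) {
        a <- verts[i]; b <- verts[if (i == len) 1L else i + 1L]
        id <- eid[a, b]
        if (id == 0L) { ok <- FALSE; break }
        eids[i] <- id
      }
      if (!ok || anyDuplicated(eids)) next
      key <- paste(sort(eids), collapse = ",")
      if (is.null(cand[[key]])) cand[[key]] <- list(len = len, verts = verts, eids = eids)
    }
  }
  keys <- ls(cand)
  if (length(keys) == 0L) stop("cycle-space rank positive but no candidate cycles found")
  lens <- vapply(keys, function(k) cand[[k]]$len, 0L)
  ord <- order(lens, keys)

  basis <- list()       # reduced GF(2) vectors
  pivots <- integer()
  chosen <- list()
  for (k in keys[ord]) {
    vec <- rep(FALSE, m)
    vec[cand[[k]]$eids] <- TRUE
    for (b in seq_along(basis)) {
      if (vec[pivots[b]]) vec <- xor(vec, basis[[b]])
    }
    if (any(vec)) {
      basis[[length(basis) + 1L]] <- vec
      pivots <- c(pivots, which(vec)[1L])
      chosen[[length(chosen) + 1L]] <- cand[[k]]$verts
      if (length(chosen) == rank_target) break
    }
  }
  if (length(chosen) != rank_target) {
    stop("failed to extract a full cycle basis")    # should be unreachable
  }
  chosen
}

#' Identify rings in the carbon skeleton
#'
#' Computes a minimum cycle basis (smallest-set-of-smallest-rings
#' equivalent) of the connected carbon skeleton. For planar fused
#' benzenoids this coincides with the hexagonal faces. The number of rings
#' equals the cycle-space dimension E - V + 1.
#'
#' @param graph a typed `bfhc_graph` (see [build_typed_graph()]).
#' @param max_ring_size largest basis cycle accepted (default 7; PAH rings
#'   are 5-, 6- or 7-membered; macrocycles are out of scope).
#' @return An object of class `bfhc_rings`: `rings` (list of ordered carbon
#'   index cycles, molecule indexing), `membership` (per-atom count of
#'   containing rings, 0 for hydrogens), `edge_ring_count` (n x n integer
#'   matrix; boundary edges have count 1), `carbons` (skeleton atoms used),
#'   and `has_non_hexagon` (flag for 5-/7-membered rings).
#' @export
find_rings <- function(graph, max_ring_size = 7L) {
  stopifnot(inherits(graph, "bfhc_graph"))
  frags <- graph$carbon_fragments
  carbons <- frags[[which.max(vapply(frags, length, 0L))]]
  if (length(frags) > 1L) {
    warning(sprintf("multiple fused components (%d); analysing the largest (%d carbons)",
                    length(frags), length(carbons)), call. = FALSE)
  }
  sub <- graph$adjacency[carbons, carbons, drop = FALSE]
  cycles_local <- minimum_cycle_basis(sub)
  rings <- lapply(cycles_local, function(v) carbons[v])
  sizes <- lengths(rings)
  if (any(sizes > max_ring_size)) {
    stop(sprintf("basis cycle of size %d exceeds max_ring_size = %d (macrocycles out of scope)",
                 max(sizes), max_ring_size), call. = FALSE)
  }
  n <- graph$molecule$n
  membership <- integer(n)
  edge_ring_count <- matrix(0L, n, n)
  for (ring in rings) {
    membership[ring] <- membership[ring] + 1L
    len <- length(ring)
    for (i in seq_len(len)) {
      a <- ring[i]; b <- ring[if (i == len) 1L else i + 1L]
      edge_ring_count[a, b] <- edge_ring_count[a, b] + 1L
      edge_ring_count[b, a] <- edge_ring_count[b, a] + 1L
    }
  }
  structure(
    list(rings = rings, membership = membership,
         edge_ring_count = edge_ring_count, carbons = carbons,
         has_non_hexagon = any(sizes != 6L)),
    class = "bfhc_rings"
  )
}

#' @export
print.bfhc_rings <- function(x, ...) {
  cat(sprintf("<bfhc_rings> %d ring(s), sizes: %s\n", length(x$rings),
              paste(lengths(x$rings), collapse = ", ")))
  invisible(x)
}

#' Ordered walk along the outer perimeter of a fused ring system
#'
#' Boundary edges are the ring edges belonging to exactly one basis ring;
#' for a simply connected fused system they form a single closed walk.
#' Substituent atoms (sp3 / branch carbons outside all rings) are excluded
#' from the walk but recorded as decorations on their anchor carbons.
#'
#' @param rings a `bfhc_rings` from [find_rings()].
#' @param graph the matching typed `bfhc_graph`.
#' @return A list: `walk` (ordered cyclic vector of carbon indices),
#'   `is_junction` (logical per walk position; `TRUE` when the carbon
#'   belongs to >= 2 rings), `decorations` (named list mapping walk carbons
#'   to non-ring carbon substituent indices).
#' @export
boundary_walk <- function(rings, graph) {
  stopifnot(inherits(rings, "bfhc_rings"), inherits(graph, "bfhc_graph"))
  if (length(rings$rings) == 0L) stop("no rings: boundary walk undefined", call. = FALSE)
  erc <- rings$edge_ring_count
  bnd <- erc == 1L
  bdeg <- rowSums(bnd)
  verts <- which(bdeg > 0L)
  if (any(bdeg[verts] != 2L)) {
    stop("boundary is not a single closed walk (vertex with boundary degree != 2)",
         call. = FALSE)
  }
  start <- min(verts)
  nxt <- min(which(bnd[start, ]))
  walk <- c(start, nxt)
  prev <- start
  cur <- nxt
  while (TRUE) {
    step <- setdiff(which(bnd[cur, ]), prev)
    if (length(step) != 1L) stop("boundary walk is ambiguous", call. = FALSE)
    if (step == start) break
    walk <- c(walk, step)
    prev <- cur
    cur <- step
  }
  if (length(walk) != length(verts)) {
    stop("multiple boundary cycles: ring system is not simply connected", call. = FALSE)
  }
  ring_atoms <- unique(unlist(rings$rings))
  deco <- lapply(walk, function(v) {
    nb <- which(graph$adjacency[v, ])
    nb[graph$molecule$symbols[nb] == "C" & !(nb %in% ring_atoms)]
  })
  names(deco) <- as.character(walk)
  list(walk = walk,
       is_junction = rings$membership[walk] >= 2L,
       decorations = deco[lengths(deco) > 0L])
}

# Inner dual adjacency: rings sharing >= 2 atoms (a fused bond).
ring_dual_adjacency <- function(rings) {
  nr <- length(rings$rings)
  dual <- matrix(FALSE, nr, nr)
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) {
      for (j in seq(i + 1L, nr)) {
        if (length(intersect(rings$rings[[i]], rings$rings[[j]])) >= 2L) {
          dual[i, j] <- dual[j, i] <- TRUE
        }
      }
    }
  }
  dual
}

#' Classify fused-ring topology
#'
#' Three classes: `peri-condensed` iff any carbon belongs to three or more
#' rings (pyrene-type clusters); otherwise the system is cata-condensed and
#' subdivided into `linear` (the inner dual graph is a simple path and every
#' internal ring's two fused neighbors lie on opposite sides -- operationally
#' the angle at each internal ring centroid between its neighbor centroids is
#' at least `linear_angle_threshold` degrees) or `angular` (bent or branched
#' duals). Single-ring molecules are `linear` by convention. On an idealized
#' hexagonal lattice acenes give exactly 180 degrees and kinks 120, so any
#' threshold in (120, 180) separates them.
#'
#' @param rings a `bfhc_rings`.
#' @param graph the matching `bfhc_graph`.
#' @param linear_angle_threshold collinearity threshold in degrees
#'   (default 170).
#' @return one of `"linear"`, `"angular"`, `"peri-condensed"`.
#' @export
classify_topology <- function(rings, graph, linear_angle_threshold = 170) {
  stopifnot(inherits(rings, "bfhc_rings"))
  nr <- length(rings$rings)
  if (nr == 0L) stop("no rings: topology classification undefined", call. = FALSE)
  if (any(rings$membership >= 3L)) return("peri-condensed")
  if (nr == 1L) return("linear")
  dual <- ring_dual_adjacency(rings)
  deg <- rowSums(dual)
  # a tree path: all dual degrees <= 2, connected, nr - 1 edges
  if (any(deg > 2L) || sum(dual) / 2 != nr - 1L || any(deg == 0L)) {
    return("angular")
  }
  centroids <- t(vapply(rings$rings, function(r) {
    colMeans(graph$molecule$coords[r, , drop = FALSE])
  }, numeric(3)))
  internal <- which(deg == 2L)
  for (i in internal) {
    nb <- which(dual[i, ])
    u <- centroids[nb[1L], ] - centroids[i, ]
    v <- centroids[nb[2L], ] - centroids[i, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    if (ang < linear_angle_threshold) return("angular")
  }
  "linear"
}
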