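# Shared test helpers: rigid-body transforms, permutations, and compact
# accessors for pipeline quantities.

# random proper rotation (det +1), or improper (reflection) when mirror = TRUE
random_rotation <- function(mirror = FALSE) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if ((det(q) < 0) != mirror) q[, 1] <- -q[, 1]
  q
}

transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  molecule(mol$symbols,
           sweep(mol$coords %*% t(rotation), 2L, -translation),
           title = mol$title)
}

permute_molecule <- function(mol, perm) {
  molecule(mol$symbols[perm], mol$coords[perm, , drop = FALSE], title = mol$title)
}

bfhc_counts <- function(res) {
  unname(res$motifs$counts[c("bay", "fjord", "harbor", "canyon")])
}

# counts comparable between detector and oracle (no extended: the oracle's
# path cutoff is 7 atoms)
oracle_kinds <- c("fissure", "bay", "fjord", "harbor", "canyon")

canonical_motif_paths <- function(report) {
  keys <- vapply(report$motifs, function(m) {
    p <- m$path
    if (p[1] > p[length(p)]) p <- rev(p)
    paste(m$kind, paste(p, collapse = "-"))
  }, "")
  sort(keys)
}

# full pipeline on a builder fixture, geometry filter off unless stated
analyse <- function(mol, ...) bfhc_compute(mol, ...)
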