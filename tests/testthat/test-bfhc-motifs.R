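# bfhc_motifs: run-length detection, brute-force oracle equivalence,
# conservation, geometry filter, endpoint policy, serialization.

pipeline <- function(mol, ...) {
  g <- build_typed_graph(mol)
  rs <- find_rings(g)
  list(graph = g, rings = rs,
       detect = detect_motifs(rs, g, ...),
       oracle = brute_force_motifs(rs, g))
}

test_that("canonical fixtures carry the expected BFHC counts (oracle-checked)", {
  expected <- list(   #            bay fjord harbor canyon
    phenanthrene           = c(1, 0, 0, 0),
    chrysene               = c(2, 0, 0, 0),
    triphenylene           = c(3, 0, 0, 0),
    "benzo[c]phenanthrene" = c(0, 1, 0, 0),
    pentahelicene          = c(0, 0, 1, 0),
    hexahelicene           = c(0, 0, 0, 1),
    anthracene             = c(0, 0, 0, 0),
    pyrene                 = c(0, 0, 0, 0),
    coronene               = c(0, 0, 0, 0),
    "benzo[a]pyrene"       = c(1, 0, 0, 0),
    perylene               = c(2, 0, 0, 0)
  )
  for (nm in names(expected)) {
    p <- pipeline(canonical(nm)$molecule)
    for (rep in list(p$detect, p$oracle)) {
      expect_equal(unname(rep$counts[c("bay", "fjord", "harbor", "canyon")]),
                   expected[[nm]], label = nm)
    }
  }
})

test_that("phenanthrene decomposes into one bay and two fissures with a 4-atom path", {
  p <- pipeline(canonical("phenanthrene")$molecule)
  expect_equal(unname(p$detect$counts[["fissure"]]), 2L)
  bays <- Filter(function(m) m$kind == "bay", p$detect$motifs)
  expect_length(bays, 1L)
  expect_length(bays[[1]]$path, 4L)
  # endpoints are rim sp2-H carbons, interior atoms are junctions
  expect_equal(bays[[1]]$endpoint_types, c("sp2-H", "sp2-H"))
  interior <- bays[[1]]$path[2:3]
  expect_true(all(p$rings$membership[interior] >= 2L))
  # endpoints not bonded
  expect_false(p$graph$adjacency[bays[[1]]$path[1], bays[[1]]$path[4]])
})

test_that("helicene series: path lengths grow 5, 6, 7 with exactly one motif each", {
  cases <- list("benzo[c]phenanthrene" = c("fjord", 5L),
                pentahelicene = c("harbor", 6L),
                hexahelicene = c("canyon", 7L))
  for (nm in names(cases)) {
    p <- pipeline(canonical(nm)$molecule)
    hits <- Filter(function(m) m$kind == cases[[nm]][1], p$detect$motifs)
    expect_length(hits, 1L)
    expect_length(hits[[1]]$path, as.integer(cases[[nm]][2]))
    expect_true(hits[[1]]$passed_geometry)
  }
})

test_that("benzene yields an empty report", {
  p <- pipeline(canonical("benzene")$molecule)
  expect_equal(sum(p$detect$counts), 0L)
  expect_length(p$oracle$motifs, 0L)
})

test_that("detector (geometry off) equals oracle on all canonical fixtures", {
  for (nm in canonical_names()) {
    p <- pipeline(canonical(nm)$molecule, geometry_filter = FALSE)
    expect_equal(p$detect$counts[oracle_kinds], p$oracle$counts[oracle_kinds],
                 label = nm)
    expect_equal(canonical_motif_paths(p$detect), canonical_motif_paths(p$oracle),
                 label = nm)
  }
})

test_that("detector equals oracle on random polyhexes", {
  for (seed in 1:25) {
    n_cells <- 2L + (seed %% 6L)
    b <- build_benzenoid(random_polyhex(n_cells, seed))
    p <- pipeline(b$molecule, geometry_filter = FALSE)
    expect_equal(p$detect$counts[oracle_kinds], p$oracle$counts[oracle_kinds],
                 label = sprintf("polyhex seed %d", seed))
    expect_equal(canonical_motif_paths(p$detect), canonical_motif_paths(p$oracle))
  }
})

test_that("boundary decomposition conserves junction carbons", {
  # fissure + 2 bay + 3 fjord + 4 harbor + 5 canyon (+ extended) = junctions
  for (nm in canonical_names()) {
    p <- pipeline(canonical(nm)$molecule, geometry_filter = FALSE)
    cnt <- p$detect$counts
    lhs <- cnt[["fissure"]] + 2L * cnt[["bay"]] + 3L * cnt[["fjord"]] +
      4L * cnt[["harbor"]] + 5L * cnt[["canyon"]]
    expect_equal(lhs, p$detect$n_boundary_junction, label = nm)
  }
})

test_that("counts are invariant under rigid motion, reflection, permutation", {
  set.seed(99)
  for (nm in c("chrysene", "hexahelicene", "benzo[a]pyrene")) {
    mol <- canonical(nm)$molecule
    base <- pipeline(mol)$detect$counts
    for (rep in 1:5) {
      m2 <- permute_molecule(
        transform_molecule(mol, random_rotation(mirror = rep %% 2 == 0),
                           stats::rnorm(3, sd = 5)),
        sample(mol$n))
      expect_equal(pipeline(m2)$detect$counts, base,
                   label = sprintf("%s rep %d", nm, rep))
    }
  }
})

test_that("geometry filter retains failing motifs but excludes them from counts", {
  mol <- canonical("hexahelicene")$molecule
  g <- build_typed_graph(mol)
  rs <- find_rings(g)
  # canyon endpoints sit 4.0 A apart (5 cells x 0.8 A rise): a 3.5 A cap fails it
  strict <- detect_motifs(rs, g, geometry_max_distance = 3.5)
  expect_equal(unname(strict$counts[["canyon"]]), 0L)
  canyon <- Filter(function(m) m$kind == "canyon", strict$motifs)
  expect_length(canyon, 1L)
  expect_false(canyon[[1]]$passed_geometry)
  expect_equal(canyon[[1]]$endpoint_distance, 4.0, tolerance = 1e-6)
  # disabling the filter reproduces pure-topology counts
  off <- detect_motifs(rs, g, geometry_filter = FALSE)
  expect_equal(unname(off$counts[["canyon"]]), 1L)
})

test_that("endpoint policy: substituted flanks count under 'any' only", {
  b <- canonical("phenanthrene")
  res <- bfhc_compute(b$molecule)
  bay_path <- Filter(function(m) m$kind == "bay", res$motifs$motifs)[[1]]$path
  mb <- methylate(b, bay_path[1])
  expect_equal(bfhc_compute(mb$molecule)$record$bay, 1L)
  expect_equal(bfhc_compute(mb$molecule, endpoint_policy = "hydrogen-only")$record$bay, 0L)
})

test_that("reports serialize deterministically and round-trip through JSON", {
  p <- pipeline(canonical("phenanthrene")$molecule)
  tab <- report_motifs(p$detect, "table")
  expect_match(tab[1], "kind\tpath_indices")
  expect_length(tab, 1L + length(p$detect$motifs))
  bay_rows <- grep("^bay\t", tab)
  expect_length(bay_rows, 1L)
  # 0-based, 4-atom path
  expect_match(tab[bay_rows], "\\t[0-9]+-[0-9]+-[0-9]+-[0-9]+\\t")

  js <- report_motifs(p$detect, "json")
  back <- motif_report_from_json(js)
  expect_equal(back$counts, p$detect$counts)
  expect_equal(canonical_motif_paths(back), canonical_motif_paths(p$detect))
  expect_identical(report_motifs(back, "json"), js)

  empty <- pipeline(canonical("benzene")$molecule)$detect
  expect_length(report_motifs(empty, "table"), 1L)   # headers only
})
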