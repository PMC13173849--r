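# dataset_tools: table ingest, ordinal encoding, cross-validation, summary.

toy_csv <- function() {
  paste(
    "id,iupac_name,xyz_file,n_carbon,n_hydrogen,bay,fjord,harbor,canyon,topology,carcinogenicity,log_p,log_iball",
    "p1,phenanthrene,p1.xyz,14,10,1,0,0,0,angular,-,4.46,",
    "p2,benzo[a]pyrene,p2.xyz,20,12,1,0,0,0,peri-condensed,H,6.13,2.67",
    sep = "\n")
}

test_that("reading a well-formed table yields typed records", {
  tab <- read_pah_table(toy_csv())
  expect_s3_class(tab, "pah_table")
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$bay, c(1L, 1L))
  expect_identical(tab$carcinogenicity, c("-", "H"))
  expect_true(is.na(tab$log_iball[1]))
  expect_equal(tab$log_iball[2], 2.67)
})

test_that("header matching is case/spacing-insensitive and mappable", {
  hdr <- "ID,IUPAC Name,PAH xyz input file,Carbon,Hydrogen,Bay,Fjord,Harbor,Canyon,Topology class,Carcinogenicity,Log P,Log Iball"
  row <- "x,pyrene,x.xyz,16,10,0,0,0,0,Peri-condensed (clustered),M,4.88,1.0"
  tab <- read_pah_table(paste(hdr, row, sep = "\n"))
  expect_equal(tab$n_carbon, 16L)
  expect_equal(tab$topology, "peri-condensed")
  # explicit column_map overrides
  hdr2 <- sub("Log Iball", "Potency index", hdr)
  expect_error(read_pah_table(paste(hdr2, row, sep = "\n")), "log_iball")
  tab2 <- read_pah_table(paste(hdr2, row, sep = "\n"),
                         column_map = c(log_iball = "Potency index"))
  expect_equal(tab2$log_iball, 1.0)
})

test_that("vocabulary and integer violations are rejected with row context", {
  bad_label <- sub("angular,-", "angular,X", toy_csv())
  expect_error(read_pah_table(bad_label), "unknown carcinogenicity label 'X'")
  bad_count <- sub("14,10,1", "14,10,1.5", toy_csv())
  expect_error(read_pah_table(bad_count), "non-integer")
})

test_that("the '+' alias resolves to LM with a log entry", {
  aliased <- sub("peri-condensed,H", "peri-condensed,+", toy_csv())
  expect_message(tab <- read_pah_table(aliased), "alias '\\+' -> 'LM'")
  expect_equal(tab$carcinogenicity[2], "LM")
  expect_identical(attr(tab, "alias_log"), "p2")
})

test_that("ordinal encoding follows the seven-level order", {
  expect_identical(encode_carcinogenicity(c("-", "±", "L", "LM", "M", "HM", "H")),
                   0:6)
  expect_identical(encode_carcinogenicity("+"), 3L)       # alias then encode
  expect_error(encode_carcinogenicity("Z"), "unknown")
  # encode-decode identity, strict monotonicity
  labs <- carcinogenicity_levels
  expect_identical(decode_carcinogenicity(encode_carcinogenicity(labs)), labs)
  expect_true(all(diff(encode_carcinogenicity(labs)) > 0))
  # alternative reading: L collapses to non-carcinogenic
  expect_identical(encode_carcinogenicity("L", collapse_L_to_negative = TRUE), 0L)
  expect_identical(encode_carcinogenicity("M", collapse_L_to_negative = TRUE), 4L)
})

test_that("tables round-trip through CSV exactly, missing stays missing", {
  tab <- read_pah_table(toy_csv())
  path <- withr::local_tempfile(fileext = ".csv")
  write_pah_table(tab, path)
  back <- read_pah_table(path)
  for (col in pah_table_columns) {
    expect_identical(back[[col]], tab[[col]], label = col)
  }
})

test_that("cross-validation flags injected faults and missing files only", {
  dir <- withr::local_tempdir()
  names <- c("phenanthrene", "pyrene", "hexahelicene")
  for (nm in names) {
    write_xyz(canonical(nm)$molecule, file.path(dir, paste0(nm, ".xyz")))
  }
  tab <- bfhc_compute_files(file.path(dir, paste0(names, ".xyz")))
  tab$carcinogenicity <- c("-", "-", "M")

  clean <- cross_validate(tab, dir)
  expect_equal(clean$n_valid, 3L)
  expect_equal(nrow(clean$count_mismatches), 0L)

  tab2 <- tab
  tab2$bay[1] <- tab2$bay[1] + 1L
  faulty <- cross_validate(tab2, dir)
  expect_equal(nrow(faulty$count_mismatches), 1L)
  expect_equal(faulty$count_mismatches$id, "phenanthrene")
  expect_equal(faulty$count_mismatches$field, "bay")

  tab3 <- tab
  tab3$xyz_file[2] <- "missing.xyz"
  partial <- cross_validate(tab3, dir)
  expect_length(partial$unreadable, 1L)
  expect_equal(partial$n_valid, 2L)
})

test_that("summaries count records, non-missing properties, distinct labels", {
  tab <- read_pah_table(toy_csv())
  tab$log_p[1] <- NA
  s <- summarize_pah_table(tab)
  expect_equal(s$n_records, 2L)
  expect_equal(s$n_logp, 1L)
  expect_equal(s$n_logiball, 1L)
  expect_equal(s$n_distinct_carcinogenicity_labels, 2L)
  # permutation invariance
  s2 <- summarize_pah_table(tab[2:1, ])
  expect_equal(s2[c("n_records", "n_logp", "n_logiball")],
               s[c("n_records", "n_logp", "n_logiball")])
  expect_error(summarize_pah_table(tab[0, ]), "empty")
})

test_that("the bundled synthetic example table is internally consistent", {
  path <- system.file("extdata", "pah_table_synthetic.csv", package = "bfhc")
  tab <- read_pah_table(path)
  expect_equal(nrow(tab), 15L)
  # recompute every structural field from the builder
  for (i in seq_len(nrow(tab))) {
    rec <- bfhc_compute(canonical(tab$id[i])$molecule, id = tab$id[i])$record
    for (f in c("n_carbon", "n_hydrogen", "bay", "fjord", "harbor", "canyon", "topology")) {
      expect_identical(tab[[f]][i], rec[[f]][1], label = paste(tab$id[i], f))
    }
  }
})
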