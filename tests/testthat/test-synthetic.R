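test_that("every generator is byte-deterministic per seed", {
  expect_identical(make_protein_db(5, c(50, 100), seed = 1),
                   make_protein_db(5, c(50, 100), seed = 1))
  accs <- sprintf("P%02d", 1:10)
  expect_identical(make_knowledgebase(accs, 3, c(3, 5), 12, seed = 2),
                   make_knowledgebase(accs, 3, c(3, 5), 12, seed = 2))
  truth <- list(de_proteins = accs[1:2],
                planted_folds = setNames(c(2, 2), accs[1:2]),
                accessions = accs)
  expect_identical(make_spot_table(truth, 10, 0.1, seed = 3),
                   make_spot_table(truth, 10, 0.1, seed = 3))
  db <- make_protein_db(5, c(80, 150), seed = 1)
  expect_identical(make_peak_lists(db, names(db), seed = 4),
                   make_peak_lists(db, names(db), seed = 4))
  expect_identical(make_densitometry(0.1, 0.05, 4, seed = 5),
                   make_densitometry(0.1, 0.05, 4, seed = 5))
})

test_that("protein records honor count, length and digestibility", {
  db <- make_protein_db(5, c(50, 100), seed = 1)
  expect_length(db, 5)
  expect_true(all(nchar(db) >= 50 & nchar(db) <= 100))
  expect_true(all(strsplit(paste(db, collapse = ""), "")[[1]] %in%
                    names(protpipe::RESIDUE_MASS)))
  expect_error(make_protein_db(0), ">= 1")
  db2 <- make_protein_db(100, c(100, 400), seed = 7)
  ok <- vapply(db2, function(s) {
    mz <- unlist(lapply(digest(s, 1), peptide_mz))
    any(mz >= 800 & mz <= 3000)
  }, TRUE)
  expect_true(all(ok))
})

test_that("knowledgebase sets and graph obey their contracts", {
  accs <- sprintf("P%02d", 1:10)
  kb <- make_knowledgebase(accs, 3, c(3, 5), 12, seed = 2)
  expect_length(kb$pathways, 3)
  expect_true(all(lengths(kb$pathways) >= 3 & lengths(kb$pathways) <= 5))
  expect_true(all(!vapply(kb$pathways, anyDuplicated, 0L) > 0))
  expect_equal(nrow(kb$edges), 12)
  expect_true(all(kb$edges$from != kb$edges$to))
  expect_false(any(duplicated(paste(pmin(kb$edges$from, kb$edges$to),
                                    pmax(kb$edges$from, kb$edges$to)))))
  # degenerate and invalid shapes
  kb0 <- make_knowledgebase(accs, 0, c(3, 5), 5, seed = 1)
  expect_length(kb0$pathways, 0)
  expect_equal(nrow(kb0$edges), 5)
  expect_error(make_knowledgebase(accs, 1, c(3, 5), 999, seed = 1),
               "exceeds")
})

test_that("spot-table calibration separates planted from null spots", {
  accs <- sprintf("P%03d", 1:200)
  de <- accs[1:20]
  truth <- list(de_proteins = de,
                planted_folds = setNames(rep(2, 20), de),
                accessions = accs)
  tab <- make_spot_table(truth, 200, cv = 0.1, seed = 3)
  nv <- normalize_volumes(tab)
  kept <- fold_filter(nv, 1.5)
  expect_gte(sum(kept$is_de), 0.8 * 20)
  expect_lte(sum(!kept$is_de), 0.05 * 180)
})

test_that("noiseless peak lists equal the in-silico digest", {
  db <- make_protein_db(5, c(100, 200), seed = 6)
  pk <- make_peak_lists(db, names(db)[1], detect_prob = 1,
                        ppm_jitter = 0, n_background = 0, seed = 1)
  expected <- unique(sort(unlist(lapply(
    digest(db[[1]], 1), peptide_mz, n_oxidized_met = 0))))
  expected <- expected[expected >= 800 & expected <= 3000]
  expect_equal(pk$peak_lists[[1]]$mz, expected)
  expect_true(all(diff(pk$peak_lists[[1]]$mz) > 0))
  expect_true(all(pk$peak_lists[[1]]$intensity > 0))
  # empty identity set is an empty batch, not an error
  empty <- make_peak_lists(db, character(0))
  expect_length(empty$peak_lists, 0)
})

test_that("densitometry log-ratios have the planted location and scale", {
  d0 <- make_densitometry(0.3, sigma = 1e-9, n_replicates = 4, seed = 2)
  expect_equal(normalize_blots(d0)$y, rep(0.3, 4), tolerance = 1e-6)
  dn <- make_densitometry(0, sigma = 0.05, n_replicates = 50, seed = 3)
  y <- normalize_blots(dn)$y
  expect_lt(abs(mean(y)), 3 * 0.05 / sqrt(50))
  expect_error(make_densitometry(0.1, 0.05, 1), ">= 2")
})

test_that("generated files round-trip through the package readers", {
  study <- make_synthetic_study(seed = 9, n_proteins = 12, n_spots = 12,
                                n_de = 2, n_pathways = 3,
                                pathway_size = c(3, 6), n_edges = 30)
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  expect_identical(read_fasta(paths[["fasta"]]), study$db)
  expect_identical(read_gmt(paths[["gmt"]]), study$kb$pathways)
  expect_equal(read_sif(paths[["sif"]]), study$kb$edges)
  mgf <- read_mgf(paths[["mgf"]])
  expect_identical(names(mgf), names(study$peaks$peak_lists))
  for (id in names(mgf))
    expect_equal(mgf[[id]]$mz, study$peaks$peak_lists[[id]]$mz,
                 tolerance = 1e-6)
  sp <- read_spot_csv(paths[["spots"]])
  expect_equal(sp$raw_A, study$spots$raw_A)
  dd <- read_densitometry_csv(paths[["densitometry"]])
  expect_equal(dd$target_density, study$densitometry$target_density)
  tr <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(tr$de_proteins, study$truth$de_proteins)
})

test_that("two-column text peak lists parse with comments and commas", {
  f <- withr::local_tempfile(lines = c("# spectrum", "900.5 12",
                                       "1200.25,30", "", "850.1\t7"))
  pl <- read_peaklist(f)
  expect_equal(pl$mz, c(850.1, 900.5, 1200.25))
  expect_equal(pl$intensity, c(7, 12, 30))
})
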