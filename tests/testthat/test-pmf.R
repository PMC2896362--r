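test_that("ppm matching is inclusive at the tolerance boundary", {
  m <- match_peaks(1000.05, 1000.00, tolerance_ppm = 50)
  expect_equal(nrow(m), 1)
  expect_equal(m$ppm, 50, tolerance = 1e-6)
  expect_equal(nrow(match_peaks(1000, 1000, 50)), 1)       # 0 ppm
  expect_equal(nrow(match_peaks(2000.2, 2000.0, 50)), 0)   # 100 ppm
})

test_that("each observed peak matches its nearest theoretical mass only", {
  m <- match_peaks(1000.01, c(1000.00, 1000.03), tolerance_ppm = 50)
  expect_equal(m$theo, 1000.00)
  expect_equal(m$ppm, 10, tolerance = 1e-6)
  m2 <- match_peaks(1000.025, c(1000.00, 1000.03), tolerance_ppm = 50)
  expect_equal(m2$theo, 1000.03)
  # duplicated theoretical masses collapse to one match per peak
  m3 <- match_peaks(1000.00, c(1000.00, 1000.00), tolerance_ppm = 50)
  expect_equal(nrow(m3), 1)
})

test_that("background bins are removed above, kept at, the occurrence cut", {
  b15 <- occurrence_batch(n_lists = 20, n_with_bin = 3)  # 15%
  f15 <- filter_background(b15, occurrence_threshold = 0.10)
  expect_equal(nrow(f15$removed), 1)
  expect_equal(f15$removed$occurrence, 0.15)
  expect_false(any(vapply(f15$batch, function(p)
    any(abs(p$mz - 1500) < 1), TRUE)))

  b10 <- occurrence_batch(n_lists = 20, n_with_bin = 2)  # exactly 10%
  f10 <- filter_background(b10, occurrence_threshold = 0.10)
  expect_equal(nrow(f10$removed), 0)
  expect_equal(sum(vapply(f10$batch, nrow, 0L)), sum(vapply(b10, nrow, 0L)))
})

test_that("background filtering refuses meaninglessly small batches", {
  expect_error(filter_background(occurrence_batch(n_lists = 5)),
               "at least 10")
})

test_that("background filtering is invariant to batch order", {
  b <- occurrence_batch(n_lists = 20, n_with_bin = 5, jitter_ppm = 10)
  f1 <- filter_background(b)
  f2 <- filter_background(rev(b))
  expect_equal(f1$removed$bin_mz, f2$removed$bin_mz)
  expect_equal(unname(lapply(f1$batch, `[[`, "mz")),
               unname(rev(lapply(f2$batch, `[[`, "mz"))))
})

test_that("planted jittered background bins are found exactly", {
  study <- make_synthetic_study(seed = 5, n_proteins = 20, n_spots = 20,
                                n_de = 4, n_background = 5,
                                background_occurrence = 0.5,
                                ppm_jitter = 10)
  f <- filter_background(study$peaks$peak_lists)
  # every planted contaminant bin is eliminated ...
  expect_true(all(vapply(study$peaks$background_mz, function(b)
    any(abs(b - f$removed$bin_mz) / b * 1e6 < 50), TRUE)))
  # ... and the high-occurrence removals are exactly the planted bins
  # (low-occurrence removals can arise from chance peptide-mass
  # collisions between unrelated proteins)
  high <- f$removed$bin_mz[f$removed$occurrence >= 0.3]
  expect_length(high, length(study$peaks$background_mz))
})

test_that("the shared-peak scorer counts exactly the matched peaks", {
  db <- toy_db()
  cfg <- pmf_config(missed_cleavages = 0)
  # spectrum of P1: all three of its tryptic peptides
  mzs <- sort(unlist(lapply(digest(db[["P1"]], 0), peptide_mz,
                            config = cfg, n_oxidized_met = 0)))
  peaks <- data.frame(mz = mzs, intensity = 1)
  sc <- score_candidates(peaks, db, cfg)
  p1 <- sc[sc$accession == "P1", ]
  p2 <- sc[sc$accession == "P2", ]
  expect_equal(p1$score1, 3)  # shares 2 with P2, owns 1
  expect_equal(p2$score1, 2)
  expect_equal(p1$rank1, 1)
  expect_equal(p1$matched, p1$score1)  # internal consistency oracle
  expect_true(p1$consensus)
})

test_that("a spectrum matching nothing yields no identification", {
  peaks <- data.frame(mz = c(801.5, 1201.5, 2901.5), intensity = 1)
  sc <- score_candidates(peaks, toy_db(), pmf_config(missed_cleavages = 0))
  expect_true(all(sc$score1 == 0))
  expect_true(all(!sc$consensus))
  expect_true(all(is.infinite(sc$rank1)))
})

test_that("noiseless planted spectra rank their protein first everywhere", {
  study <- make_synthetic_study(seed = 2, n_proteins = 15, n_spots = 15,
                                n_de = 2, detect_prob = 1, ppm_jitter = 0,
                                n_background = 0)
  pl <- study$peaks$peak_lists[[1]]
  truth_acc <- study$peaks$identity[[1]]
  sc <- score_candidates(pl, study$db)
  best <- sc[1, ]
  expect_equal(best$accession, truth_acc)
  expect_equal(best$rank1, 1)
  expect_equal(best$rank2, 1)
  expect_equal(best$rank3, 1)
  expect_true(best$consensus)
})

test_that("Mr/pI agreement flags plausible identifications", {
  db <- c(A1 = strrep("ACDEFGHIKLMNPQRSTVWY", 10))
  mr <- protein_mass(db[["A1"]]) / 1000
  pi <- isoelectric_point(db[["A1"]])
  expect_true(check_mr_pi("A1", mr * 1.1, pi + 0.5, db)$consistent)
  expect_false(check_mr_pi("A1", mr * 1.5, pi, db)$consistent)
  expect_false(check_mr_pi("A1", mr, pi + 2, db)$consistent)
  expect_error(check_mr_pi("nope", mr, pi, db), "not in database")
})
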