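make_assigned_spectrum <- function(mz, intensity, snr, formula, status,
                                   id) {
  sp <- data.frame(mz = mz, intensity = intensity, snr = snr,
                   formula = formula, error_ppm = 0, status = status,
                   stringsAsFactors = FALSE)
  attr(sp, "sample_id") <- id
  sp
}

test_that("alignment keys assigned peaks by formula across spectra", {
  s1 <- make_assigned_spectrum(179.0561, 100, 10, "C6H12O6", "assigned",
                               "a")
  s2 <- make_assigned_spectrum(179.0561, 150, 12, "C6H12O6", "assigned",
                               "b")
  m <- align_peaks(list(a = s1, b = s2), make_meta(c("a", "b")))
  expect_equal(nrow(m$intensity), 1)
  expect_equal(as.numeric(m$intensity["C6H12O6", ]), c(100, 150))
})

test_that("unassigned peaks cluster by single linkage within tolerance", {
  s1 <- make_assigned_spectrum(300.00000, 100, 10, NA, "no_candidate", "a")
  s2 <- make_assigned_spectrum(300.00010, 120, 10, NA, "no_candidate", "b")
  meta <- make_meta(c("a", "b"))
  # 0.33 ppm gap < 0.5 ppm tolerance: one feature
  m <- align_peaks(list(a = s1, b = s2), meta, tol_ppm = 0.5)
  expect_equal(nrow(m$intensity), 1)
  # same gap > 0.1 ppm tolerance: two features
  m2 <- align_peaks(list(a = s1, b = s2), meta, tol_ppm = 0.1)
  expect_equal(nrow(m2$intensity), 2)
})

test_that("sub-threshold peaks never enter the aligned matrix", {
  s1 <- make_assigned_spectrum(c(179.0561, 300.1), c(100, 50), c(10, 3),
                               c("C6H12O6", NA), c("assigned", "sub_snr"),
                               "a")
  s2 <- make_assigned_spectrum(179.0561, 90, 9, "C6H12O6", "assigned", "b")
  s3 <- make_assigned_spectrum(179.0561, 95, 9, "C6H12O6", "assigned", "c")
  m <- align_peaks(list(a = s1, b = s2, c = s3),
                   make_meta(c("a", "b", "c")))
  expect_equal(nrow(m$intensity), 1)
})

test_that("minimum-occurrence filter keeps >= k non-blank detections", {
  ids <- c(paste0("s", 1:4), "bl")
  intensity <- rbind(
    in2 = c(5, 5, 0, 0, 10),   # 2 non-blank detections: removed
    in3 = c(5, 5, 5, 0, 0),    # boundary: kept ("at least 3")
    in4 = c(5, 5, 5, 5, 0)
  )
  colnames(intensity) <- ids
  m <- make_aligned(intensity, meta = make_meta(ids, replicate = 1:5,
                                                is_blank = c(rep(FALSE, 4),
                                                             TRUE)))
  got <- min_occurrence_filter(m, k = 3)
  expect_setequal(rownames(got$intensity), c("in3", "in4"))
  # k = 1 is the identity
  expect_equal(min_occurrence_filter(m, k = 1)$intensity, m$intensity)
  # idempotence
  expect_equal(min_occurrence_filter(got, k = 3)$intensity, got$intensity)
})

test_that("raised detection limit removes entries under 1.05x the floor", {
  ids <- c("s1", "s2")
  intensity <- rbind(f1 = c(100, 500), f2 = c(104, 500), f3 = c(106, 500))
  colnames(intensity) <- ids
  m <- make_aligned(intensity, meta = make_meta(ids))
  got <- suppressWarnings(raise_detection_limit(m, factor = 1.05))
  expect_equal(as.numeric(got$intensity[, "s1"]), c(0, 0, 106))
  # factor 1 is the identity
  expect_equal(raise_detection_limit(m, 1)$intensity, m$intensity)
  # idempotent because the original floor is recorded on the matrix
  expect_equal(suppressWarnings(raise_detection_limit(got, 1.05))$intensity,
               got$intensity)
  expect_error(raise_detection_limit(m, 0.9), ">= 1")
})

test_that("an all-equal spectrum is emptied by the raised limit", {
  ids <- c("s1", "s2")
  intensity <- rbind(f1 = c(100, 500), f2 = c(100, 600))
  colnames(intensity) <- ids
  m <- make_aligned(intensity, meta = make_meta(ids))
  expect_warning(got <- raise_detection_limit(m), "emptied")
  expect_equal(sum(got$intensity[, "s1"]), 0)
})

test_that("blank rules remove contaminated features and drop blanks", {
  ids <- c("s1", "s2", paste0("bl", 1:10))
  is_blank <- c(FALSE, FALSE, rep(TRUE, 10))
  intensity <- matrix(0, 4, 12, dimnames = list(
    c("strong_blank", "majority_blank", "clean", "blank_only"), ids))
  snr <- intensity
  # detected everywhere in samples
  intensity[, 1:2] <- 10
  snr[, 1:2] <- 4
  snr["clean", 1:2] <- 100
  # 20x rule: blank S/N 100 > 20 * sample S/N 4
  intensity["strong_blank", 3] <- 10; snr["strong_blank", 3] <- 100
  # majority rule: present in 7 of 10 blanks at low S/N
  intensity["majority_blank", 3:9] <- 10; snr["majority_blank", 3:9] <- 5
  snr["majority_blank", 1:2] <- 1000   # strong in samples: still removed
  # blank-only feature is removed too (any S/N beats zero sample signal)
  intensity["blank_only", 1:2] <- 0; snr["blank_only", 1:2] <- 0
  intensity["blank_only", 3] <- 10; snr["blank_only", 3] <- 5
  m <- make_aligned(intensity, snr,
                    make_meta(ids, replicate = 1:12, is_blank = is_blank))
  got <- blank_filter(m, ratio = 20, blank_majority = 7)
  expect_equal(rownames(got$intensity), "clean")
  expect_false(any(got$meta$is_blank))
  # blank S/N 100 vs sample S/N 100: 100 < 2000, kept
  expect_warning(blank_filter(got), "no blank")
})

test_that("replicate outliers are flagged manually or by dissimilarity", {
  ids <- paste0("r", 1:3)
  meta <- make_meta(ids)
  identical3 <- matrix(rep(c(5, 5, 5), each = 3), nrow = 3, byrow = TRUE,
                       dimnames = list(paste0("f", 1:3), ids))
  m <- make_aligned(identical3, meta = meta)
  expect_length(flag_replicate_outliers(m, "distance", threshold = 0.5), 0)

  # one replicate with zero overlap against its siblings
  disjoint <- rbind(f1 = c(0, 5, 5), f2 = c(0, 5, 5), f3 = c(9, 0, 0))
  colnames(disjoint) <- ids
  m2 <- make_aligned(disjoint, meta = meta)
  expect_equal(flag_replicate_outliers(m2, "distance", threshold = 0.5),
               "r1")

  expect_equal(flag_replicate_outliers(m, "manual", ids = "r2"), "r2")
  expect_error(flag_replicate_outliers(m, "manual", ids = ids), "all")
  expect_error(flag_replicate_outliers(m, "manual", ids = "nope"),
               "unknown")
})

test_that("normalization rescales each spectrum to unit sum", {
  ids <- c("s1", "s2")
  intensity <- rbind(C6H12O6 = c(2, 1), C7H6O2 = c(3, 0), C8H8O2 = c(5, 0),
                     mz_300.00000 = c(7, 7))
  colnames(intensity) <- ids
  m <- make_aligned(intensity, meta = make_meta(ids))
  tab <- normalize_intensities(m)
  expect_equal(as.numeric(tab[, "s1"]), c(0.2, 0.3, 0.5))
  expect_equal(as.numeric(tab[, "s2"]), c(1, 0, 0))  # single-peak spectrum
  expect_equal(colSums(tab), c(s1 = 1, s2 = 1), tolerance = 1e-12)
  # unassigned features are reported separately, not normalized away
  expect_equal(rownames(attr(tab, "unassigned")), "mz_300.00000")
  # a spectrum with no assigned signal is an error
  bad <- intensity; bad[1:3, 2] <- 0
  m2 <- make_aligned(bad, meta = make_meta(ids))
  expect_error(normalize_intensities(m2), "s2")
})

test_that("each QC filter only ever shrinks the feature set", {
  cfg <- sim_config(seed = 13, n_library = 150, n_vdom = 40, n_blanks = 4,
                    n_noise_peaks = 30, n_blank_shared = 3,
                    n_blank_unique = 3)
  sim <- simulate_experiment(generate_formula_library(cfg))
  assigned <- assign_spectra(sim$spectra)
  m <- align_peaks(assigned, sim$meta)
  stages <- list(
    raise_detection_limit(m),
    min_occurrence_filter(raise_detection_limit(m)),
    suppressWarnings(blank_filter(min_occurrence_filter(
      raise_detection_limit(m))))
  )
  prev <- rownames(m$intensity)
  for (st in stages) {
    cur <- rownames(st$intensity)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})
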