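test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(seed = 1, n_library = 100, n_vdom = 30, n_blanks = 3,
                    n_noise_peaks = 20, n_blank_shared = 2,
                    n_blank_unique = 2)
  t1 <- generate_formula_library(cfg)
  t2 <- generate_formula_library(cfg)
  expect_identical(t1$library, t2$library)
  expect_identical(t1$vdom, t2$vdom)
  s1 <- simulate_experiment(t1)
  s2 <- simulate_experiment(t2)
  expect_identical(s1$spectra, s2$spectra)
})

test_that("library formulas are distinct, valid and disjoint from vdom", {
  cfg <- sim_config(seed = 1, n_library = 200, n_vdom = 60)
  truth <- generate_formula_library(cfg)
  expect_equal(nrow(truth$library), 200)
  expect_false(anyDuplicated(truth$library$formula) > 0)
  expect_length(intersect(truth$library$formula, truth$vdom$formula), 0)
  expect_true(all(conforms_to_rules(truth$library$formula)))
  expect_true(all(conforms_to_rules(truth$vdom$formula)))
  # removed subset is a subset of the pulse
  expect_true(all(truth$vdom$formula[truth$vdom$removed] %in%
                    truth$vdom$formula))
})

test_that("vdom heteroatom content hits the configured targets", {
  cfg <- sim_config(seed = 9, n_library = 0, n_vdom = 600)
  truth <- generate_formula_library(cfg)
  expect_equal(nrow(truth$library), 0)  # degenerate empty library is fine
  f <- parse_formula(truth$vdom$formula)
  expect_lt(abs(mean(f$n > 0) - 0.63), 0.02)
  expect_lt(abs(mean(f$s > 0) - 0.28), 0.02)
  expect_lt(abs(mean(f$p > 0) - 0.20), 0.02)
  expect_equal(mean(truth$vdom$removed), 0.58, tolerance = 0.002)
})

test_that("the design arithmetic yields 48 sample spectra plus blanks", {
  cfg <- sim_config(seed = 4, n_library = 30, n_vdom = 5,
                    n_noise_peaks = 5, n_blank_shared = 2,
                    n_blank_unique = 2)
  sim <- simulate_experiment(generate_formula_library(cfg))
  expect_equal(sum(!sim$meta$is_blank), 48)  # 2 x 2 x 4 x 3
  expect_equal(sum(sim$meta$is_blank), 10)
  expect_equal(length(sim$spectra), 58)
  # spectra are sorted by m/z
  expect_true(all(vapply(sim$spectra,
                         function(s) !is.unsorted(s$mz), logical(1))))
})

test_that("zero jitter places every detected peak at its exact m/z", {
  cfg <- sim_config(seed = 4, n_library = 50, n_vdom = 0, n_blanks = 0,
                    mass_jitter_ppm_sd = 0, n_noise_peaks = 0,
                    n_blank_shared = 0, n_blank_unique = 0,
                    detection_prob_curve = function(i) rep(1, length(i)))
  truth <- generate_formula_library(cfg)
  sim <- simulate_experiment(truth)
  exact <- sort(formula_to_mz(truth$library$formula))
  for (sp in sim$spectra[1:3]) {
    expect_equal(sp$mz, exact, tolerance = 1e-12)
  }
})

test_that("full removal leaves no vdom formula in day-55 spectra", {
  cfg <- sim_config(seed = 4, n_library = 20, n_vdom = 30,
                    vdom_removal_prob = 1, mass_jitter_ppm_sd = 0,
                    n_noise_peaks = 0, n_blank_shared = 0,
                    n_blank_unique = 0,
                    detection_prob_curve = function(i) rep(1, length(i)))
  truth <- generate_formula_library(cfg)
  sim <- simulate_experiment(truth)
  vmz <- formula_to_mz(truth$vdom$formula)
  d55 <- sim$spectra[["subsurface_treatment_d55_r1"]]
  expect_false(any(vmz %in% d55$mz))
  d6 <- sim$spectra[["subsurface_treatment_d6_r1"]]
  expect_true(all(vmz %in% d6$mz))
  # the pulse never reaches the surface arms (no-induction null)
  expect_false(any(vmz %in% sim$spectra[["surface_treatment_d6_r1"]]$mz))
})

test_that("jittered peaks stay within the assignment tolerance", {
  # with jitter SD 0.05 ppm and a 0.5 ppm window, essentially every true
  # peak is inside the window (10 sigma)
  cfg <- sim_config(seed = 15, n_library = 300, n_vdom = 0, n_blanks = 0,
                    n_noise_peaks = 0, n_blank_shared = 0,
                    n_blank_unique = 0,
                    detection_prob_curve = function(i) rep(1, length(i)))
  truth <- generate_formula_library(cfg)
  sim <- simulate_experiment(truth)
  exact <- sort(formula_to_mz(truth$library$formula))
  offs <- unlist(lapply(sim$spectra, function(sp) {
    (sp$mz - exact) / exact * 1e6
  }))
  expect_gt(mean(abs(offs) <= 0.5), 0.999)
  expect_lt(abs(sd(offs) - 0.05), 0.01)
})

test_that("OTU scenarios shape evenness as designed", {
  stab <- generate_otu_table("stabilized", seed = 6, depth_reads = 15000)
  expect_identical(stab$counts,
                   generate_otu_table("stabilized", seed = 6,
                                      depth_reads = 15000)$counts)
  dv <- rarefy_bootstrap(stab$counts, depth = 11000, boots = 10, seed = 6)
  expect_lt(max(dv$pielou_mean) - min(dv$pielou_mean), 0.05)

  bloom <- generate_otu_table("bloom", seed = 6, depth_reads = 15000)
  db <- rarefy_bootstrap(bloom$counts, depth = 11000, boots = 10, seed = 6)
  expect_lt(db$pielou_mean[db$sample == "d55"],
            db$pielou_mean[db$sample == "d0"])
  expect_error(generate_otu_table("bloom", n_otus = 1), "n_otus")
  expect_error(generate_otu_table("bloom", depth_reads = 0), "depth_reads")
})

test_that("environmental tables are positive, reproducible and trend-true", {
  cfg <- sim_config(seed = 2, n_library = 10, n_vdom = 0, n_noise_peaks = 0)
  sim <- simulate_experiment(generate_formula_library(cfg))
  env <- generate_env_table(sim$meta, seed = 2)
  expect_true(all(as.matrix(env) > 0))
  expect_identical(env, generate_env_table(sim$meta, seed = 2))
  # zero noise: replicates identical, trends exactly linear in day
  env0 <- generate_env_table(sim$meta, seed = 2, noise_sd = 0)
  m <- sim$meta[!sim$meta$is_blank, ]
  sel <- m$sample_id[m$depth == "subsurface" & m$arm == "treatment" &
                       m$replicate == 1]
  doc <- env0[sel, "DOC"]
  days <- m$day[match(sel, m$sample_id)]
  fit <- lm(doc ~ days)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  # the virus-to-cell ratio climbs from ~34 to ~77 upon induction
  vcr <- virus_to_cell_ratio(env0[sel, "VLP"], env0[sel, "TCC"])
  expect_equal(vcr[days == 0], 34, tolerance = 0.01)
  # VLP plateaus at 77x the initial TCC while TCC declines slightly
  expect_equal(vcr[days == 14], 79, tolerance = 1)
})
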