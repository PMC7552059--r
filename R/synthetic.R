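#' Simulation configuration
#'
#' Parameters of the synthetic incubation experiment. The defaults encode
#' the study conditions being emulated: 2 depths x treatment/control x
#' 4 time points x 3 analytical replicates plus 10 blanks; a lysis pulse
#' of 1230 biomolecule-like formulas injected into the subsurface
#' treatment at day 6, of which 63% contain N, 28% S and 20% P
#' (allocated by exact counts); 58% of the pulse is removed by day 55;
#' mass jitter of 0.05 ppm (instrument calibration error < 0.07 ppm).
#' Intensities are log-normal (the intensity distribution of DOM peaks is
#' an assumption, exposed here); detection is Bernoulli with a logistic
#' probability curve in log10 intensity.
#'
#' @param seed RNG seed (mandatory; there is no nondeterministic default).
#' @param n_library number of background formulas shared by all samples.
#' @param n_vdom number of injected lysis-pulse formulas.
#' @param vdom_heteroatom_targets named fractions (`n`, `s`, `p`) of
#'   vDOM formulas containing each heteroatom.
#' @param vdom_removal_prob fraction of the pulse undetectable by day 55.
#' @param mass_jitter_ppm_sd Gaussian m/z error SD in ppm.
#' @param n_noise_peaks spurious peaks per sample spectrum.
#' @param detection_prob_curve monotone map intensity -> detection
#'   probability.
#' @param n_blanks number of blank spectra.
#' @param replicates analytical replicates per condition.
#' @param intensity_meanlog,intensity_sdlog log-normal base intensity.
#' @param replicate_sdlog per-sample log-normal intensity scatter.
#' @param snr_unit detector units per unit of S/N (S/N = intensity/unit).
#' @param noise_snr_below4_frac fraction of noise peaks drawn below
#'   S/N 4.
#' @param day14_attenuation,day55_attenuation intensity attenuation of
#'   the surviving pulse at the later time points (two-point decay model).
#' @param n_blank_shared library-derived blank contaminants exercising
#'   the 20x S/N blank rule.
#' @param n_blank_unique blank-specific contaminants exercising the
#'   7-of-10 blank rule.
#' @param blank_carryover_prob probability a library formula leaks into
#'   any given blank at trace level.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_library = 5000,
                       n_vdom = 1230,
                       vdom_heteroatom_targets = c(n = 0.63, s = 0.28,
                                                   p = 0.20),
                       vdom_removal_prob = 0.58,
                       mass_jitter_ppm_sd = 0.05,
                       n_noise_peaks = 400,
                       detection_prob_curve = function(intensity) {
                         plogis((log10(pmax(intensity, 1)) - 3.5) / 0.3)
                       },
                       n_blanks = 10,
                       replicates = 3,
                       intensity_meanlog = log(5e5),
                       intensity_sdlog = 0.9,
                       replicate_sdlog = 0.2,
                       snr_unit = 250,
                       noise_snr_below4_frac = 0.5,
                       day14_attenuation = 0.6,
                       day55_attenuation = 0.6,
                       n_blank_shared = 15,
                       n_blank_unique = 15,
                       blank_carryover_prob = 0.02) {
  if (missing(seed)) stop("a seed is mandatory for the simulation")
  probs <- c(vdom_heteroatom_targets, vdom_removal_prob,
             noise_snr_below4_frac, blank_carryover_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(n_library >= 0, n_vdom >= 0, n_blanks >= 0, replicates >= 1,
            mass_jitter_ppm_sd >= 0, is.function(detection_prob_curve))
  structure(as.list(environment()), class = "sim_config")
}

# Draw one batch of random rule-conformant formulas. profile controls the
# chemical region: "background" spans the usual DOM van Krevelen space,
# "biomolecule" the H-rich (H/C >= ~1.3) region typical of fresh cell
# material. nsp, when given, fixes heteroatom counts per row.
.draw_formula_batch <- function(n, profile, nsp = NULL,
                                rules = assignment_rules()) {
  if (profile == "background") {
    c_ <- pmin(pmax(round(rlnorm(n, log(18), 0.30)), 5L), 45L)
    hc <- runif(n, 0.6, 1.8)
    oc <- runif(n, 0.1, 0.9)
  } else {
    c_ <- pmin(pmax(round(rlnorm(n, log(16), 0.30)), 5L), 35L)
    hc <- runif(n, 1.3, 2.2)
    oc <- runif(n, 0.2, 0.8)
  }
  if (is.null(nsp)) {
    nn <- sample(0:4, n, replace = TRUE, prob = c(.44, .33, .14, .06, .03))
    ss <- sample(0:2, n, replace = TRUE, prob = c(.90, .09, .01))
    pp <- sample(0:1, n, replace = TRUE, prob = c(.985, .015))
  } else {
    nn <- nsp$n; ss <- nsp$s; pp <- nsp$p
  }
  h_ <- round(c_ * hc)
  # force integer DBE: h + n + p must be even
  odd <- (h_ + nn + pp) %% 2 == 1
  h_[odd] <- h_[odd] + 1L
  o_ <- pmin(round(c_ * oc), 60L)
  data.frame(c = as.integer(c_), h = as.integer(h_), n = as.integer(nn),
             o = as.integer(o_), s = as.integer(ss), p = as.integer(pp))
}

# TRUE where the formula's exact neutral mass resolves back to itself
# under the assignment rules (unique within tolerance after the
# double-assignment ladder).
.uniquely_assignable <- function(f, rules) {
  if (nrow(f) == 0) return(logical(0))
  key <- format_formula(f)
  cand <- .enumerate_bulk(monoisotopic_mass(f), rules)
  cand$formula <- format_formula(cand[.ELEMENTS])
  vapply(seq_len(nrow(f)), function(i) {
    block <- cand[cand$query == i, , drop = FALSE]
    res <- resolve_double_assignments(block)
    !is.null(res) && res$formula[1] == key[i]
  }, logical(1))
}

.sample_formulas <- function(n, profile, exclude = character(0),
                             nsp = NULL, rules = assignment_rules(),
                             mz_limits = MASS_WINDOW) {
  if (n == 0) {
    out <- .empty_formula_df(0L)
    out$formula <- character(0)
    return(out)
  }
  fixed <- !is.null(nsp)
  need <- seq_len(n)
  acc <- vector("list", 0)
  keys <- character(0)
  rows_pending <- if (fixed) nsp else NULL
  guard <- 0
  while (length(need) > 0) {
    guard <- guard + 1
    if (guard > 200) stop("formula sampling failed to converge")
    batch <- .draw_formula_batch(length(need), profile,
                                 nsp = rows_pending, rules = rules)
    key <- format_formula(batch)
    mz <- formula_to_mz(batch)
    ok <- conforms_to_rules(batch, rules) &
      mz >= mz_limits[1] & mz <= mz_limits[2] &
      !(key %in% exclude) & !(key %in% keys) & !duplicated(key)
    # the ground truth emulates identifiable DOM: compositions whose
    # exact mass cannot be uniquely resolved are excluded at the source
    ok[ok] <- .uniquely_assignable(batch[ok, , drop = FALSE], rules)
    if (any(ok)) {
      kept <- batch[ok, , drop = FALSE]
      kept$formula <- key[ok]
      kept$.slot <- need[ok]
      acc[[length(acc) + 1]] <- kept
      keys <- c(keys, key[ok])
    }
    need <- need[!ok]
    if (fixed) rows_pending <- nsp[need, , drop = FALSE]
  }
  out <- do.call(rbind, acc)
  out <- out[order(out$.slot), , drop = FALSE]
  out$.slot <- NULL
  rownames(out) <- NULL
  out
}

#' Generate the ground-truth formula library
#'
#' Draws the background library, the vDOM pulse (with heteroatom
#' membership and the removed subset allocated by exact counts so the
#' configured rates are the simulation's ground truth), and the blank
#' contaminant sets. All formulas are rule-conformant, mutually distinct,
#' and deterministic under the seed.
#'
#' @param config a [sim_config()].
#' @return list of class `ground_truth`: `library` (formula,
#'   base_intensity, shared_contaminant flag), `vdom` (formula,
#'   base_intensity, removed flag), `blank_unique` (formula,
#'   base_intensity), and `config`.
#' @export
generate_formula_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tg <- config$vdom_heteroatom_targets
  if (sum(tg) > 3) stop("infeasible heteroatom targets")
  with_seed(config$seed, {
    lib <- .sample_formulas(config$n_library, "background")
    lib$base_intensity <- rlnorm(nrow(lib), config$intensity_meanlog,
                                 config$intensity_sdlog)
    lib$shared_contaminant <- rep(FALSE, nrow(lib))
    if (config$n_blank_shared > 0 && nrow(lib) > 0) {
      idx <- sample.int(nrow(lib), min(config$n_blank_shared, nrow(lib)))
      lib$shared_contaminant[idx] <- TRUE
      # contaminants ride near the detection limit in real samples
      lib$base_intensity[idx] <- runif(length(idx), 2200, 3500)
    }

    nv <- config$n_vdom
    if (nv > 0) {
      nsp <- data.frame(n = integer(nv), s = integer(nv), p = integer(nv))
      nsp$n[sample.int(nv, round(tg[["n"]] * nv))] <-
        sample(1:4, round(tg[["n"]] * nv), replace = TRUE,
               prob = c(.55, .30, .10, .05))
      nsp$s[sample.int(nv, round(tg[["s"]] * nv))] <-
        sample(1:2, round(tg[["s"]] * nv), replace = TRUE, prob = c(.85, .15))
      nsp$p[sample.int(nv, round(tg[["p"]] * nv))] <- 1L
      # keep combined heteroatom counts assignable (N + S + P cap) while
      # preserving which formulas contain each heteroatom
      cap <- assignment_rules()$max_heteroatoms
      over <- nsp$n + nsp$s + nsp$p > cap
      nsp$n[over] <- pmax(ifelse(nsp$n[over] > 0, 1L, 0L),
                          cap - nsp$s[over] - nsp$p[over])
      vdom <- .sample_formulas(nv, "biomolecule", exclude = lib$formula,
                               nsp = nsp)
      vdom$base_intensity <- rlnorm(nv, config$intensity_meanlog,
                                    config$intensity_sdlog)
      vdom$removed <- FALSE
      vdom$removed[sample.int(nv, round(config$vdom_removal_prob * nv))] <- TRUE
    } else {
      vdom <- .empty_formula_df(0L)
      vdom$formula <- character(0)
      vdom$base_intensity <- numeric(0)
      vdom$removed <- logical(0)
    }

    # blank contaminants emulate small solvent/instrument molecules
    blank_unique <- .sample_formulas(
      config$n_blank_unique, "background",
      exclude = c(lib$formula, vdom$formula),
      mz_limits = c(MASS_WINDOW[1], 600))
    if (nrow(blank_unique) > 0) {
      blank_unique$base_intensity <- runif(nrow(blank_unique), 2e4, 6e4)
    } else {
      blank_unique$base_intensity <- numeric(0)
    }

    structure(list(library = lib, vdom = vdom, blank_unique = blank_unique,
                   config = config),
              class = "ground_truth")
  })
}

.jitter_mz <- function(mz, ppm_sd) {
  if (ppm_sd == 0) return(mz)
  mz * (1 + rnorm(length(mz), 0, ppm_sd * 1e-6))
}

.noise_peaks <- function(n, config) {
  if (n == 0) {
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0)))
  }
  below <- runif(n) < config$noise_snr_below4_frac
  data.frame(
    mz = runif(n, MASS_WINDOW[1], MASS_WINDOW[2]),
    intensity = rlnorm(n, log(1500), 0.5),
    snr = ifelse(below, runif(n, 1.5, 4), runif(n, 4, 10))
  )
}

#' Simulate the incubation experiment
#'
#' Produces one spectrum per (depth x arm x day x replicate) plus the
#' blanks. Every true formula appears as its \[M-H\]- m/z with Gaussian
#' ppm jitter; detection is Bernoulli under the configured probability
#' curve; the vDOM pulse is added to the subsurface treatment from day 6
#' (the surface arms simulate the no-induction null), attenuated at days
#' 14/55 and stripped of the removed subset at day 55. Blanks carry the
#' planted contaminants, trace library carryover and noise.
#'
#' @param truth a `ground_truth` from [generate_formula_library()].
#' @param config a [sim_config()] (defaults to `truth$config`).
#' @return list with `spectra` (named list of peak-list data frames) and
#'   `meta` (sample metadata data frame).
#' @export
simulate_experiment <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  design <- expand.grid(replicate = seq_len(config$replicates),
                        day = DESIGN_DAYS,
                        arm = c("treatment", "control"),
                        depth = c("surface", "subsurface"),
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_d%d_r%d", design$depth, design$arm,
                              design$day, design$replicate)
  meta <- data.frame(sample_id = design$sample_id, depth = design$depth,
                     arm = design$arm, day = design$day,
                     replicate = design$replicate, is_blank = FALSE,
                     stringsAsFactors = FALSE)
  if (config$n_blanks > 0) {
    meta <- rbind(meta, data.frame(
      sample_id = sprintf("blank_r%d", seq_len(config$n_blanks)),
      depth = NA_character_, arm = "blank", day = NA_integer_,
      replicate = seq_len(config$n_blanks), is_blank = TRUE))
  }

  lib <- truth$library
  vdom <- truth$vdom
  bu <- truth$blank_unique
  exact_mz_lib <- formula_to_mz(lib)
  exact_mz_vdom <- formula_to_mz(vdom)
  exact_mz_bu <- formula_to_mz(bu)

  with_seed(config$seed + 1L, {
    # fixed blank membership: which blanks carry each planted contaminant
    .membership <- function(n_feat, n_in) {
      t(vapply(seq_len(n_feat), function(i) {
        seq_len(config$n_blanks) %in%
          sample.int(config$n_blanks, min(n_in, config$n_blanks))
      }, logical(config$n_blanks)))
    }
    blank_slots <- list(
      shared = .membership(sum(lib$shared_contaminant), 5),
      unique = .membership(nrow(bu), 9)
    )
    spectra <- list()
    for (i in seq_len(nrow(meta))) {
      row <- meta[i, ]
      if (!row$is_blank) {
        atten <- 1
        mzs <- exact_mz_lib
        ints <- lib$base_intensity
        if (nrow(bu) > 0) {
          mzs <- c(mzs, exact_mz_bu)
          ints <- c(ints, bu$base_intensity)
        }
        pulse <- row$depth == "subsurface" && row$arm == "treatment" &&
          row$day >= 6 && nrow(vdom) > 0
        if (pulse) {
          keep <- if (row$day >= 55) !vdom$removed else rep(TRUE, nrow(vdom))
          at <- if (row$day == 6) 1 else if (row$day == 14)
            config$day14_attenuation else config$day55_attenuation
          mzs <- c(mzs, exact_mz_vdom[keep])
          ints <- c(ints, vdom$base_intensity[keep] * at)
        }
        ints <- ints * rlnorm(length(ints), 0, config$replicate_sdlog)
        det <- runif(length(ints)) < config$detection_prob_curve(ints)
        real <- data.frame(
          mz = .jitter_mz(mzs[det], config$mass_jitter_ppm_sd),
          intensity = ints[det],
          snr = ints[det] / config$snr_unit
        )
        sp <- rbind(real, .noise_peaks(config$n_noise_peaks, config))
      } else {
        b <- row$replicate  # blank index
        parts <- list(.noise_peaks(100, config))
        shared <- which(lib$shared_contaminant)
        if (length(shared) > 0) {
          # each shared contaminant sits in exactly 5 of the blanks
          # (below the majority rule) at S/N far above its sample level,
          # exercising the 20x rule
          in_this <- shared[blank_slots[["shared"]][, b]]
          if (length(in_this) > 0) {
            snr_b <- runif(length(in_this), 800, 2500)
            parts[[length(parts) + 1]] <- data.frame(
              mz = .jitter_mz(exact_mz_lib[in_this],
                              config$mass_jitter_ppm_sd),
              intensity = snr_b * config$snr_unit, snr = snr_b)
          }
        }
        if (nrow(bu) > 0) {
          # blank-specific contaminants appear in exactly 9 of 10 blanks,
          # exercising the majority rule
          in_this <- which(blank_slots[["unique"]][, b])
          if (length(in_this) > 0) {
            snr_b <- runif(length(in_this), 100, 300)
            parts[[length(parts) + 1]] <- data.frame(
              mz = .jitter_mz(exact_mz_bu[in_this],
                              config$mass_jitter_ppm_sd),
              intensity = snr_b * config$snr_unit, snr = snr_b)
          }
        }
        carry <- which(runif(nrow(lib)) < config$blank_carryover_prob)
        if (length(carry) > 0) {
          ci <- lib$base_intensity[carry] * 0.05
          parts[[length(parts) + 1]] <- data.frame(
            mz = .jitter_mz(exact_mz_lib[carry], config$mass_jitter_ppm_sd),
            intensity = ci, snr = ci / config$snr_unit)
        }
        sp <- do.call(rbind, parts)
      }
      sp <- sp[sp$mz >= MASS_WINDOW[1] & sp$mz <= MASS_WINDOW[2], ,
               drop = FALSE]
      sp <- sp[order(sp$mz), , drop = FALSE]
      rownames(sp) <- NULL
      attr(sp, "sample_id") <- row$sample_id
      spectra[[row$sample_id]] <- sp
    }
    list(spectra = spectra, meta = meta)
  })
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic OTU table
#'
#' Dirichlet-multinomial OTU counts over the four incubation time points.
#' The `stabilized` scenario keeps the community composition constant in
#' expectation; the `bloom` scenario (a "bottle effect") progressively
#' concentrates read mass onto a few copiotrophic OTUs, so evenness
#' decreases over time.
#'
#' @param scenario `"bloom"` or `"stabilized"`.
#' @param n_otus number of OTUs (>= 2).
#' @param depth_reads reads per sample (>= 1).
#' @param seed RNG seed.
#' @param n_bloom number of blooming OTUs (bloom scenario).
#' @param concentration Dirichlet concentration (larger = less
#'   sample-to-sample noise).
#' @return list with `counts` (OTUs x days matrix, columns `d0, d6, d14,
#'   d55`) and `taxonomy` (class-level label per OTU; blooming OTUs are
#'   Gammaproteobacteria).
#' @export
generate_otu_table <- function(scenario = c("stabilized", "bloom"),
                               n_otus = 300, depth_reads = 25000, seed = 1,
                               n_bloom = 3, concentration = 5000) {
  scenario <- match.arg(scenario)
  if (n_otus < 2) stop("n_otus must be >= 2")
  if (depth_reads < 1) stop("depth_reads must be >= 1")
  classes <- c("Gammaproteobacteria", "Flavobacteriia",
               "Deltaproteobacteria", "Alphaproteobacteria",
               "Planctomycetacia", "Anaerolineae", "Bacteroidia",
               "Clostridia")
  with_seed(seed, {
    base <- rgamma(n_otus, shape = 0.8)
    base <- base / sum(base)
    taxonomy <- sample(classes, n_otus, replace = TRUE,
                       prob = c(.2, .15, .15, .15, .1, .1, .1, .05))
    bloom_idx <- order(base, decreasing = TRUE)[seq_len(min(n_bloom, n_otus))]
    taxonomy[bloom_idx] <- "Gammaproteobacteria"
    bloom_profile <- base * 0.1
    bloom_profile[bloom_idx] <- (0.9 / sum(seq_len(length(bloom_idx)))) *
      rev(seq_len(length(bloom_idx)))
    bloom_profile <- bloom_profile / sum(bloom_profile)
    w <- if (scenario == "bloom") c(0, 0.3, 0.6, 0.85) else rep(0, 4)
    counts <- sapply(seq_along(DESIGN_DAYS), function(t) {
      p <- (1 - w[t]) * base + w[t] * bloom_profile
      p_draw <- as.numeric(.rdirichlet(1, p * concentration))
      rmultinom(1, size = depth_reads, prob = p_draw)[, 1]
    })
    dimnames(counts) <- list(sprintf("OTU%04d", seq_len(n_otus)),
                             paste0("d", DESIGN_DAYS))
    list(counts = counts, taxonomy = taxonomy)
  })
}

#' Generate a synthetic environmental-parameter table
#'
#' One numeric column per monitored parameter (DOC, DCAA, DCCHO, DFAA,
#' DFCHO in umol/L; TCC in cells/mL; VLP in particles/mL), one row per
#' study sample. Concentrations follow linear-in-time trends per depth
#' and arm (dissolved pools rise most in the subsurface treatment); VLP
#' in the subsurface treatment rises through day 14 so that the
#' virus-to-cell ratio climbs from ~34 to ~77, emulating a successful
#' prophage induction. Multiplicative Gaussian noise is applied unless
#' `noise_sd = 0`, in which case the trends are exact.
#'
#' @param meta sample metadata (blanks are skipped).
#' @param seed RNG seed.
#' @param noise_sd relative noise SD (default 0.03).
#' @return data frame with rownames = sample ids and the seven parameter
#'   columns.
#' @export
generate_env_table <- function(meta, seed = 1, noise_sd = 0.03) {
  study <- meta[!meta$is_blank, , drop = FALSE]
  base <- list(
    DOC   = c(surface = 300, subsurface = 800),
    DCAA  = c(surface = 1.5, subsurface = 4.0),
    DCCHO = c(surface = 2.0, subsurface = 5.0),
    DFAA  = c(surface = 0.6, subsurface = 0.4),
    DFCHO = c(surface = 0.3, subsurface = 0.5)
  )
  slope <- list(  # relative change over the 55 days, by depth/arm
    DOC   = c(surface_treatment = 0.05, surface_control = 0.02,
              subsurface_treatment = 0.56, subsurface_control = 0.30),
    DCAA  = c(surface_treatment = 0.05, surface_control = 0.02,
              subsurface_treatment = 0.50, subsurface_control = 0.25),
    DCCHO = c(surface_treatment = 0.05, surface_control = 0.02,
              subsurface_treatment = 0.40, subsurface_control = 0.20),
    DFAA  = c(surface_treatment = 0.10, surface_control = 0.00,
              subsurface_treatment = 0.60, subsurface_control = 0.00),
    DFCHO = c(surface_treatment = 0.10, surface_control = 0.00,
              subsurface_treatment = 0.50, subsurface_control = 0.00)
  )
  tcc_base <- c(surface = 2e9, subsurface = 4.4e8)
  with_seed(seed, {
    out <- data.frame(row.names = study$sample_id)
    key <- paste(study$depth, study$arm, sep = "_")
    frac <- study$day / 55
    for (param in names(base)) {
      v <- base[[param]][study$depth] * (1 + slope[[param]][key] * frac)
      out[[param]] <- as.numeric(v)
    }
    tcc <- tcc_base[study$depth] *
      (1 - ifelse(study$arm == "treatment", 0.10, 0.05) * frac)
    vlp <- ifelse(study$depth == "surface", 6e10, 2.2e10)
    induced <- study$depth == "subsurface" & study$arm == "treatment"
    vlp[induced] <- 34 * 4.4e8 +
      (77 - 34) * 4.4e8 * pmin(study$day[induced], 14) / 14
    out$TCC <- as.numeric(tcc)
    out$VLP <- as.numeric(vlp)
    if (noise_sd > 0) {
      for (param in names(out)) {
        out[[param]] <- out[[param]] *
          (1 + rnorm(nrow(out), 0, noise_sd))
      }
    }
    out
  })
}

#' Write a simulated experiment to disk
#'
#' Writes per-spectrum peak lists, the sample table, the ground-truth
#' ledger, and (optionally) OTU and environmental tables as tab-separated
#' text under `dir`.
#'
#' @param sim result of [simulate_experiment()].
#' @param truth the matching `ground_truth`.
#' @param dir output directory (created if needed).
#' @param otu optional result of [generate_otu_table()].
#' @param env optional result of [generate_env_table()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, truth, dir, otu = NULL, env = NULL) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(sim$spectra)) {
    write_peaklist(sim$spectra[[id]], file.path(dir, "peaks",
                                                paste0(id, ".tsv")))
  }
  write.table(sim$meta[c("sample_id", "depth", "arm", "day", "replicate")],
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ledger <- rbind(
    data.frame(formula = truth$library$formula, role = ifelse(
      truth$library$shared_contaminant, "library_contaminant", "library")),
    data.frame(formula = truth$vdom$formula,
               role = ifelse(truth$vdom$removed, "vdom_removed",
                             "vdom_persistent")),
    data.frame(formula = truth$blank_unique$formula,
               role = "blank_contaminant")
  )
  write.table(ledger, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(otu)) {
    df <- data.frame(otu_id = rownames(otu$counts),
                     taxonomy = otu$taxonomy, otu$counts,
                     check.names = FALSE)
    write.table(df, file.path(dir, "otu.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(env)) {
    write.table(data.frame(sample_id = rownames(env), env,
                           check.names = FALSE),
                file.path(dir, "env.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}
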