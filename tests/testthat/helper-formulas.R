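# Random rule-conformant formulas by rejection sampling over the raw
# element grid (no identifiability filtering), used for property tests.
random_conformant_formulas <- function(n, seed, rules = assignment_rules(),
                                       mass_max = Inf) {
  set.seed(seed)
  acc <- NULL
  while (is.null(acc) || nrow(acc) < n) {
    m <- n * 3
    cand <- data.frame(
      c = sample(rules$c_range[1]:min(rules$c_range[2], 60), m, TRUE),
      h = sample(rules$h_range[1]:min(rules$h_range[2], 120), m, TRUE),
      n = sample(rules$n_range[1]:rules$n_range[2], m, TRUE),
      o = sample(rules$o_range[1]:min(rules$o_range[2], 40), m, TRUE),
      s = sample(rules$s_range[1]:rules$s_range[2], m, TRUE),
      p = sample(rules$p_range[1]:rules$p_range[2], m, TRUE)
    )
    ok <- conforms_to_rules(cand, rules) & monoisotopic_mass(cand) <= mass_max
    acc <- rbind(acc, cand[ok, , drop = FALSE])
    acc <- acc[!duplicated(format_formula(acc)), , drop = FALSE]
  }
  out <- acc[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random rule-conformant formulas with DOM-like composition (carbon
# numbers and element ratios spanning the background and biomolecule
# profiles), without the generator's identifiability filtering.
random_dom_formulas <- function(n, seed, rules = assignment_rules()) {
  set.seed(seed)
  acc <- NULL
  while (is.null(acc) || nrow(acc) < n) {
    m <- n * 2
    c_ <- pmin(pmax(round(rlnorm(m, log(18), 0.3)), 5L), 45L)
    h_ <- round(c_ * runif(m, 0.6, 2.2))
    nn <- sample(0:4, m, TRUE, prob = c(.44, .33, .14, .06, .03))
    ss <- sample(0:2, m, TRUE, prob = c(.90, .09, .01))
    pp <- sample(0:1, m, TRUE, prob = c(.985, .015))
    odd <- (h_ + nn + pp) %% 2 == 1
    h_[odd] <- h_[odd] + 1L
    cand <- data.frame(c = c_, h = h_, n = nn,
                       o = pmin(round(c_ * runif(m, 0.1, 0.9)), 60L),
                       s = ss, p = pp)
    acc <- rbind(acc, cand[conforms_to_rules(cand, rules), , drop = FALSE])
    acc <- acc[!duplicated(format_formula(acc)), , drop = FALSE]
  }
  out <- acc[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Construct an aligned_peaks object directly from matrices, for QC filter
# tests with hand-planted features.
make_aligned <- function(intensity, snr = NULL, meta, detection_limit = NULL,
                         formulas = NULL) {
  if (is.null(snr)) snr <- intensity / 10
  feats <- rownames(intensity)
  if (is.null(formulas)) {
    formulas <- ifelse(grepl("^mz_", feats), NA_character_, feats)
  }
  if (is.null(detection_limit)) {
    detection_limit <- apply(intensity, 2,
                             function(col) min(col[col > 0], Inf))
  }
  structure(list(
    intensity = intensity, snr = snr,
    features = data.frame(feature_id = feats, formula = formulas,
                          mz = rep(300, length(feats)),
                          stringsAsFactors = FALSE),
    meta = meta, detection_limit = detection_limit
  ), class = "aligned_peaks")
}

# Minimal metadata for a set of spectrum columns.
make_meta <- function(ids, depth = "subsurface", arm = "treatment",
                      day = 0, replicate = seq_along(ids),
                      is_blank = FALSE) {
  data.frame(sample_id = ids, depth = depth, arm = arm, day = day,
             replicate = replicate,
             is_blank = rep_len(is_blank, length(ids)),
             stringsAsFactors = FALSE)
}
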