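#' Formula assignment rules
#'
#' Bundles the tolerances and plausibility constraints used when assigning
#' CHNOSP molecular formulas to measured masses of singly deprotonated
#' ions. Element maxima N <= 4, S <= 2, P <= 1 match the heteroatom ladder
#' used by the double-assignment removal; C <= 100, H <= 200, O <= 60
#' cover the 92.1-2000 Da window. The H/C window \[0.3, 2.5\] and O/C cap
#' 1.2 are standard chemical-plausibility limits for natural DOM, and a
#' non-negative integer DBE is required.
#'
#' @param tolerance_ppm assignment window in ppm of the neutral mass.
#' @param c_range,h_range,n_range,o_range,s_range,p_range inclusive
#'   integer element count ranges, each `c(min, max)`.
#' @param hc_bounds allowed H/C ratio interval.
#' @param oc_max maximum O/C ratio.
#' @param max_heteroatoms maximum combined heteroatom count N + S + P.
#'   The default 5 matches the richest combined classes the
#'   double-assignment ladder enumerates (N4S, N4P); heteroatom-richer
#'   compositions (e.g. N4S2P) are chemically implausible for DOM and
#'   would otherwise create spurious mass-degenerate candidates.
#' @param min_snr minimum signal-to-noise ratio for a peak to be eligible
#'   for assignment.
#' @return object of class `assignment_rules`.
#' @export
assignment_rules <- function(tolerance_ppm = 0.5,
                             c_range = c(1L, 100L),
                             h_range = c(1L, 200L),
                             n_range = c(0L, 4L),
                             o_range = c(0L, 60L),
                             s_range = c(0L, 2L),
                             p_range = c(0L, 1L),
                             hc_bounds = c(0.3, 2.5),
                             oc_max = 1.2,
                             max_heteroatoms = 5L,
                             min_snr = 4) {
  stopifnot(tolerance_ppm > 0, min_snr >= 0,
            length(hc_bounds) == 2, hc_bounds[1] < hc_bounds[2], oc_max > 0)
  for (rg in list(c_range, h_range, n_range, o_range, s_range, p_range)) {
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 0) {
      stop("element ranges must be non-empty c(min, max) with min >= 0")
    }
  }
  structure(list(
    tolerance_ppm = tolerance_ppm,
    c_range = as.integer(c_range), h_range = as.integer(h_range),
    n_range = as.integer(n_range), o_range = as.integer(o_range),
    s_range = as.integer(s_range), p_range = as.integer(p_range),
    hc_bounds = hc_bounds, oc_max = oc_max,
    max_heteroatoms = as.integer(max_heteroatoms), min_snr = min_snr
  ), class = "assignment_rules")
}

#' Check formulas against assignment rules
#'
#' @param f formulas (data frame of counts or character vector).
#' @param rules an [assignment_rules()] object.
#' @return logical vector, TRUE where the formula is rule-conformant.
#' @export
conforms_to_rules <- function(f, rules = assignment_rules()) {
  f <- as_formula_df(f)
  d <- dbe(f)
  f$c >= rules$c_range[1] & f$c <= rules$c_range[2] &
    f$h >= rules$h_range[1] & f$h <= rules$h_range[2] &
    f$n >= rules$n_range[1] & f$n <= rules$n_range[2] &
    f$o >= rules$o_range[1] & f$o <= rules$o_range[2] &
    f$s >= rules$s_range[1] & f$s <= rules$s_range[2] &
    f$p >= rules$p_range[1] & f$p <= rules$p_range[2] &
    f$h / f$c >= rules$hc_bounds[1] & f$h / f$c <= rules$hc_bounds[2] &
    f$o / f$c <= rules$oc_max &
    f$n + f$s + f$p <= rules$max_heteroatoms &
    d >= 0 & abs(d - round(d)) < 1e-9
}

.enumerate_bulk <- function(masses, rules) {
  cpp_enumerate_formulas(
    as.numeric(masses), rules$tolerance_ppm,
    rules$c_range[1], rules$c_range[2],
    rules$h_range[1], rules$h_range[2],
    rules$n_range[2], rules$o_range[2], rules$s_range[2], rules$p_range[2],
    rules$hc_bounds[1], rules$hc_bounds[2], rules$oc_max,
    rules$max_heteroatoms
  )
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Finds every rule-conformant CHNOSP formula whose monoisotopic mass lies
#' within the ppm tolerance of the query mass. The search loops over the
#' heteroatom grid (N, S, P, O) and solves for the carbon/hydrogen pair in
#' the residual mass band; at sub-mDa tolerances each carbon count admits
#' at most one hydrogen count, making the inner step O(1).
#'
#' @param mass neutral monoisotopic mass (Da), scalar.
#' @param rules an [assignment_rules()] object.
#' @return data frame of candidates with columns `c,h,n,o,s,p`, `formula`
#'   and `error_ppm`, sorted by absolute mass error. Zero rows if no
#'   formula fits.
#' @export
enumerate_candidates <- function(mass, rules = assignment_rules()) {
  stopifnot(length(mass) == 1, is.finite(mass), mass > 0)
  res <- .enumerate_bulk(mass, rules)
  res <- res[order(abs(res$error_ppm)), , drop = FALSE]
  res$query <- NULL
  res <- res[c("c", "h", "n", "o", "s", "p", "error_ppm")]
  res$formula <- format_formula(res[.ELEMENTS])
  rownames(res) <- NULL
  res
}

# Heteroatom deletion ladder for double assignments, in the applied order;
# each entry is an exact (n, s, p) pattern.
.HETEROATOM_PRIORITY <- list(
  NSP = c(1L, 1L, 1L), N2S = c(2L, 1L, 0L), N3S = c(3L, 1L, 0L),
  N4S = c(4L, 1L, 0L), N2P = c(2L, 0L, 1L), N3P = c(3L, 0L, 1L),
  N4P = c(4L, 0L, 1L), NS2 = c(1L, 2L, 0L), S2P = c(0L, 2L, 1L)
)

#' Resolve multiply assigned peaks by heteroatom priority
#'
#' When more than one candidate formula fits a peak, candidates whose
#' (N, S, P) composition exactly matches the patterns NSP, N2S, N3S, N4S,
#' N2P, N3P, N4P, NS2, S2P are deleted in that order, stopping as soon as
#' a single candidate remains. If several candidates survive the full
#' pass, the peak keeps no formula at all.
#'
#' @param candidates candidate data frame as returned by
#'   [enumerate_candidates()].
#' @return a single-row data frame (the retained formula) or `NULL` when
#'   no unambiguous assignment exists.
#' @export
resolve_double_assignments <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  if (nrow(candidates) == 1) return(candidates)
  keep <- candidates
  for (pat in .HETEROATOM_PRIORITY) {
    drop <- keep$n == pat[1] & keep$s == pat[2] & keep$p == pat[3]
    keep <- keep[!drop, , drop = FALSE]
    if (nrow(keep) <= 1) break
  }
  if (nrow(keep) == 1) keep else NULL
}

#' Assign molecular formulas to a spectrum
#'
#' Applies the minimum signal-to-noise threshold, converts each surviving
#' peak's m/z to a neutral mass assuming \[M-H\]-, enumerates candidate
#' formulas within tolerance and resolves double assignments by the
#' heteroatom priority ladder.
#'
#' @param spectrum a spectrum data frame (`mz`, `intensity`, `snr`) as read
#'   by [read_peaklist()].
#' @param rules an [assignment_rules()] object.
#' @return the spectrum with added columns `formula` (Hill string or `NA`),
#'   `error_ppm`, and `status` (one of `"assigned"`, `"ambiguous"`,
#'   `"no_candidate"`, `"sub_snr"`).
#' @export
assign_spectrum <- function(spectrum, rules = assignment_rules()) {
  sp <- as.data.frame(spectrum)
  stopifnot(all(c("mz", "intensity", "snr") %in% names(sp)))
  n <- nrow(sp)
  sp$formula <- rep(NA_character_, n)
  sp$error_ppm <- rep(NA_real_, n)
  sp$status <- rep("sub_snr", n)
  if (n == 0) {
    attr(sp, "sample_id") <- attr(spectrum, "sample_id")
    return(sp)
  }
  eligible <- which(sp$snr >= rules$min_snr)
  sp$status[eligible] <- "no_candidate"
  if (length(eligible) > 0) {
    masses <- mz_to_neutral_mass(sp$mz[eligible])
    cand <- .enumerate_bulk(masses, rules)
    if (nrow(cand) > 0) {
      cand$formula <- format_formula(cand[.ELEMENTS])
      by_query <- split(cand, cand$query)
      for (key in names(by_query)) {
        block <- by_query[[key]]
        i <- eligible[as.integer(key)]
        if (nrow(block) > 1) sp$status[i] <- "ambiguous"
        res <- resolve_double_assignments(block)
        if (!is.null(res)) {
          sp$formula[i] <- res$formula[1]
          sp$error_ppm[i] <- res$error_ppm[1]
          sp$status[i] <- "assigned"
        }
      }
    }
  }
  n_assigned <- sum(sp$status == "assigned")
  vdom_log("assign_spectrum: %d/%d peaks >= S/N %.3g, %d assigned",
           length(eligible), n, rules$min_snr, n_assigned)
  attr(sp, "sample_id") <- attr(spectrum, "sample_id")
  sp
}

#' Assign a list of spectra
#'
#' @param spectra named list of spectrum data frames.
#' @param rules an [assignment_rules()] object.
#' @return named list of assigned spectra (see [assign_spectrum()]).
#' @export
assign_spectra <- function(spectra, rules = assignment_rules()) {
  lapply(spectra, assign_spectrum, rules = rules)
}
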