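#' Double-bond equivalents
#'
#' DBE = 1 + (2C - H + N + P) / 2, the ring-plus-double-bond count implied
#' by an elemental composition. For assignable formulas the value is a
#' non-negative integer (the assignment rules enforce parity and sign);
#' the raw half-integer is returned for arbitrary compositions.
#'
#' @param f formulas (data frame of counts or character vector).
#' @return numeric vector of DBE values.
#' @examples
#' dbe("C6H6")    # 4
#' dbe("CH4")     # 0
#' dbe("C3H7NO2") # 1
#' @export
dbe <- function(f) {
  f <- as_formula_df(f)
  1 + (2 * f$c - f$h + f$n + f$p) / 2
}

#' Modified aromaticity index
#'
#' AImod = (1 + C - 0.5 O - S - 0.5 H) / (C - 0.5 O - N - S - P), treating
#' half of the oxygen as carbonyl-like. If numerator or denominator is
#' non-positive the index is 0 by convention; values are capped at 1, so
#' the result always lies in \[0, 1\]. AImod > 0.5 flags aromatic
#' structures.
#'
#' @param f formulas (data frame of counts or character vector).
#' @return numeric vector of AImod values in \[0, 1\].
#' @examples
#' aimod("C6H6")    # 0.667
#' aimod("C6H12O6") # 0 (clamped)
#' @export
aimod <- function(f) {
  f <- as_formula_df(f)
  num <- 1 + f$c - 0.5 * f$o - f$s - 0.5 * f$h
  den <- f$c - 0.5 * f$o - f$n - f$s - f$p
  out <- ifelse(num <= 0 | den <= 0, 0, pmin(num / den, 1))
  out
}

#' Compound classes used for DOM classification
#' @export
COMPOUND_CLASSES <- c("saturated", "aromatic", "highly_unsaturated",
                      "potential_protein", "unsaturated", "other")

#' Classify formulas into compound groups
#'
#' Categorises each formula by its modified aromaticity index, H/C ratio,
#' DBE and nitrogen content:
#' aromatics have AImod > 0.5; highly unsaturated compounds AImod <= 0.5
#' and H/C < 1.5; unsaturated compounds H/C >= 1.5 and DBE != 0; saturated
#' compounds DBE = 0; potential proteins H/C >= 1.5, DBE != 0 and N > 0.
#' The raw rules overlap (potential proteins satisfy the unsaturated rule),
#' so a fixed precedence makes the labels mutually exclusive:
#' saturated, then aromatic, then highly_unsaturated, then
#' potential_protein, then unsaturated, then other.
#'
#' @param f formulas (data frame of counts or character vector).
#' @return factor with levels [COMPOUND_CLASSES], one label per formula.
#' @examples
#' classify_formula(c("C6H12O6", "C3H7NO2", "C7H6O2", "C16H34O"))
#' @export
classify_formula <- function(f) {
  f <- as_formula_df(f)
  d <- dbe(f)
  ai <- aimod(f)
  hc <- f$h / f$c
  lab <- rep("other", nrow(f))
  lab[hc >= 1.5 & d != 0] <- "unsaturated"
  lab[hc >= 1.5 & d != 0 & f$n > 0] <- "potential_protein"
  lab[ai <= 0.5 & hc < 1.5] <- "highly_unsaturated"
  lab[ai > 0.5] <- "aromatic"
  lab[d == 0] <- "saturated"
  factor(lab, levels = COMPOUND_CLASSES)
}

#' Molecular indices table
#'
#' Convenience wrapper returning DBE, AImod, H/C, O/C and the compound
#' class for a set of formulas.
#'
#' @param f formulas (data frame of counts or character vector).
#' @return data frame with columns `formula`, `dbe`, `aimod`, `hc`, `oc`,
#'   `class`.
#' @export
molecular_indices <- function(f) {
  df <- as_formula_df(f)
  data.frame(
    formula = format_formula(df),
    dbe = dbe(df),
    aimod = aimod(df),
    hc = df$h / df$c,
    oc = df$o / df$c,
    class = classify_formula(df),
    stringsAsFactors = FALSE
  )
}

#' Per-sample compound-class fractions
#'
#' For a normalized formula table, computes the fraction of each sample's
#' summed signal (intensity weighting) or of its detected formulas (count
#' weighting) that falls in each compound class. Fractions sum to 1 per
#' sample.
#'
#' @param table formula table (formulas x samples matrix with Hill-string
#'   rownames, as produced by [normalize_intensities()]).
#' @param weighting `"intensity"` (relative-abundance trajectories) or
#'   `"count"` (formula-count percentages).
#' @return data frame samples x classes of fractions.
#' @export
class_fractions <- function(table, weighting = c("intensity", "count")) {
  weighting <- match.arg(weighting)
  m <- as.matrix(table)
  if (weighting == "intensity" && !isTRUE(attr(table, "normalized"))) {
    stop("intensity-weighted class fractions require a normalized table")
  }
  cls <- classify_formula(rownames(m))
  out <- matrix(0, nrow = ncol(m), ncol = length(COMPOUND_CLASSES),
                dimnames = list(colnames(m), COMPOUND_CLASSES))
  for (k in COMPOUND_CLASSES) {
    sel <- cls == k
    if (weighting == "intensity") {
      out[, k] <- colSums(m[sel, , drop = FALSE])
    } else {
      out[, k] <- colSums(m[sel, , drop = FALSE] > 0)
    }
  }
  tot <- rowSums(out)
  if (any(tot == 0)) stop("sample without any detected formula")
  as.data.frame(out / tot)
}
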