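#' Formulas present under the replicate-presence rule
#'
#' Returns the set of molecular formulas considered "present" in one
#' experimental condition (depth, arm, day). Under the default
#' `all_replicates` rule a formula counts as present only when detected
#' (intensity > 0) in every non-outlier analytical replicate of the
#' condition; `any_replicate` is the permissive alternative for
#' sensitivity analyses.
#'
#' @param table normalized `formula_table` (formulas x spectra) with a
#'   `meta` attribute, or a plain matrix plus explicit `meta`.
#' @param depth `"surface"` or `"subsurface"`.
#' @param arm `"treatment"` or `"control"`.
#' @param day integer day.
#' @param rule `"all_replicates"` or `"any_replicate"`.
#' @param meta optional metadata overriding `attr(table, "meta")`.
#' @return character vector of Hill formula strings.
#' @export
presence_set <- function(table, depth, arm, day,
                         rule = c("all_replicates", "any_replicate"),
                         meta = NULL) {
  rule <- match.arg(rule)
  if (is.null(meta)) meta <- attr(table, "meta")
  if (is.null(meta)) stop("sample metadata required")
  cols <- meta$sample_id[!meta$is_blank & meta$depth == depth &
                           meta$arm == arm & meta$day == day]
  cols <- intersect(cols, colnames(table))
  if (length(cols) == 0) {
    stop("condition not in table: ", depth, "/", arm, "/day ", day)
  }
  sub <- as.matrix(table)[, cols, drop = FALSE] > 0
  hit <- if (rule == "all_replicates") rowSums(sub) == length(cols)
         else rowSums(sub) > 0
  rownames(sub)[hit]
}

#' Identify virus-derived DOM formulas
#'
#' vDOM formulas are those present in the treatment at the induction time
#' point but neither in the corresponding control nor, at the start of
#' the experiment, in treatment or control:
#' `treat_d6 \ (ctrl_d6 U treat_d0 U ctrl_d0)`.
#'
#' @param treat_induction,ctrl_induction,treat_start,ctrl_start presence
#'   sets (character vectors of formula strings) for treatment/control at
#'   the induction day and at day 0.
#' @return character vector: the vDOM formula set, disjoint from every
#'   exclusion set.
#' @export
detect_vdom <- function(treat_induction, ctrl_induction,
                        treat_start, ctrl_start) {
  excl <- union(ctrl_induction, union(treat_start, ctrl_start))
  out <- setdiff(treat_induction, excl)
  stopifnot(length(intersect(out, excl)) == 0)
  out
}

#' Fate and composition of the vDOM set
#'
#' Tracks which vDOM formulas are still present at the final time point
#' and summarises heteroatom content. `removed_fraction` is
#' `1 - |persistent| / |vdom|`; heteroatom fractions are the share of
#' vDOM formulas containing at least one N, S or P atom respectively
#' (shares overlap and need not sum to 1).
#'
#' @param vdom character vector of vDOM formulas.
#' @param treat_final presence set of the treatment at the final day.
#' @return list of class `vdom_report`: `vdom_set`, `n_vdom`,
#'   `persistent_set`, `removed_fraction`, `heteroatom_fractions`
#'   (named n/s/p). Fractions are `NA` when `vdom` is empty.
#' @export
vdom_fate <- function(vdom, treat_final) {
  persistent <- intersect(vdom, treat_final)
  n <- length(vdom)
  if (n == 0) {
    return(structure(list(vdom_set = character(0), n_vdom = 0L,
                          persistent_set = character(0),
                          removed_fraction = NA_real_,
                          heteroatom_fractions = c(n = NA_real_, s = NA_real_,
                                                   p = NA_real_)),
                     class = "vdom_report"))
  }
  f <- parse_formula(vdom)
  structure(list(
    vdom_set = vdom,
    n_vdom = n,
    persistent_set = persistent,
    removed_fraction = 1 - length(persistent) / n,
    heteroatom_fractions = c(n = mean(f$n > 0), s = mean(f$s > 0),
                             p = mean(f$p > 0))
  ), class = "vdom_report")
}

#' @export
print.vdom_report <- function(x, ...) {
  cat(sprintf("vdom_report: %d formulas, removed fraction %.3f\n",
              x$n_vdom, x$removed_fraction))
  cat(sprintf("  heteroatom content: N %.1f%%, S %.1f%%, P %.1f%%\n",
              100 * x$heteroatom_fractions["n"],
              100 * x$heteroatom_fractions["s"],
              100 * x$heteroatom_fractions["p"]))
  invisible(x)
}

#' Share of the induction-day pool that is vDOM
#'
#' @param vdom vDOM formula set.
#' @param treat_induction presence set of the treatment at the induction
#'   day (must contain `vdom`).
#' @return `|vdom| / |treat_induction|`.
#' @export
fraction_of_total <- function(vdom, treat_induction) {
  if (length(treat_induction) == 0) stop("empty induction-day presence set")
  if (length(setdiff(vdom, treat_induction)) > 0) {
    stop("vdom must be a subset of the induction-day presence set")
  }
  length(vdom) / length(treat_induction)
}

#' Full vDOM analysis for one depth
#'
#' Convenience wrapper: builds the four presence sets, detects the vDOM
#' set, and computes its fate at the final time point.
#'
#' @param table normalized `formula_table` with `meta` attribute.
#' @param depth depth label to analyse.
#' @param day_induction induction time point (default 6).
#' @param day_final final time point (default 55).
#' @param rule replicate-presence rule.
#' @param exclude_control_all_days if TRUE, exclude formulas present in
#'   the control at any time point (stricter reading of "corresponding
#'   control").
#' @return `vdom_report` with added `fraction_of_day6_total`.
#' @export
vdom_analysis <- function(table, depth, day_induction = 6, day_final = 55,
                          rule = "all_replicates",
                          exclude_control_all_days = FALSE) {
  meta <- attr(table, "meta")
  treat_ind <- presence_set(table, depth, "treatment", day_induction, rule)
  treat_0 <- presence_set(table, depth, "treatment", 0, rule)
  ctrl_0 <- presence_set(table, depth, "control", 0, rule)
  if (exclude_control_all_days) {
    days <- sort(unique(meta$day[!meta$is_blank & meta$depth == depth &
                                   meta$arm == "control"]))
    ctrl_ind <- unique(unlist(lapply(days, function(d) {
      presence_set(table, depth, "control", d, rule)
    })))
  } else {
    ctrl_ind <- presence_set(table, depth, "control", day_induction, rule)
  }
  vdom <- detect_vdom(treat_ind, ctrl_ind, treat_0, ctrl_0)
  treat_final <- presence_set(table, depth, "treatment", day_final, rule)
  report <- vdom_fate(vdom, treat_final)
  report$fraction_of_day6_total <- if (length(treat_ind) > 0) {
    length(vdom) / length(treat_ind)
  } else NA_real_
  report
}

#' Van Krevelen coordinates for one condition
#'
#' Returns O/C and H/C coordinates, heteroatom flags, compound class and
#' mean relative intensity for formulas present in all non-outlier
#' replicates of one condition (the replicate-presence rule used for van
#' Krevelen visualisation).
#'
#' @param table normalized `formula_table` with `meta` attribute.
#' @param depth,arm,day condition selector.
#' @return data frame with columns `formula`, `oc`, `hc`, `n_flag`,
#'   `p_flag`, `class`, `mean_rel_intensity`.
#' @export
vankrevelen_coords <- function(table, depth, arm, day) {
  meta <- attr(table, "meta")
  cols <- meta$sample_id[!meta$is_blank & meta$depth == depth &
                           meta$arm == arm & meta$day == day]
  cols <- intersect(cols, colnames(table))
  if (length(cols) == 0) stop("condition not in table")
  sub <- as.matrix(table)[, cols, drop = FALSE]
  present <- rowSums(sub > 0) == length(cols)
  sub <- sub[present, , drop = FALSE]
  f <- parse_formula(rownames(sub))
  data.frame(
    formula = rownames(sub),
    oc = f$o / f$c,
    hc = f$h / f$c,
    n_flag = f$n > 0,
    p_flag = f$p > 0,
    class = classify_formula(f),
    mean_rel_intensity = rowMeans(sub),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
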