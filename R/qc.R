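#' Align assigned spectra into a peak matrix
#'
#' Builds the dataset-level features x spectra matrix. Peaks with an
#' assigned formula are keyed by that formula, so the same composition in
#' different spectra lands on one feature. Unassigned peaks at or above
#' the S/N threshold are clustered across spectra by single-linkage on
#' m/z: the pooled masses are sorted and split wherever the gap between
#' neighbours exceeds the ppm tolerance. If one spectrum contributes two
#' peaks to a feature the higher intensity is kept (collision logged).
#' Sub-threshold peaks are excluded. Each spectrum's detection limit (its
#' minimum retained intensity) is recorded once here and reused by
#' [raise_detection_limit()].
#'
#' @param assigned named list of assigned spectra ([assign_spectrum()]).
#' @param meta sample metadata ([read_sample_table()]); rownames are not
#'   required but `sample_id` must cover the names of `assigned`.
#' @param tol_ppm m/z tolerance for clustering unassigned peaks.
#' @return object of class `aligned_peaks`: list with `intensity` and
#'   `snr` matrices (0 = not detected), `features` data frame
#'   (`feature_id`, `formula`, `mz`), `meta`, and per-spectrum
#'   `detection_limit`.
#' @export
align_peaks <- function(assigned, meta, tol_ppm = 0.5) {
  stopifnot(is.list(assigned), length(assigned) > 0)
  ids <- names(assigned)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(assigned, function(s) attr(s, "sample_id"), character(1))
    names(assigned) <- ids
  }
  if (!all(ids %in% meta$sample_id)) {
    stop("spectra without metadata: ",
         paste(setdiff(ids, meta$sample_id), collapse = ", "))
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]

  long <- do.call(rbind, lapply(ids, function(id) {
    sp <- assigned[[id]]
    keep <- sp$status != "sub_snr"
    if (!any(keep)) return(NULL)
    data.frame(sample_id = id, mz = sp$mz[keep],
               intensity = sp$intensity[keep], snr = sp$snr[keep],
               formula = sp$formula[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0) stop("no peaks above S/N threshold")

  assigned_rows <- !is.na(long$formula)
  long$feature <- NA_character_
  long$feature[assigned_rows] <- long$formula[assigned_rows]

  un <- which(!assigned_rows)
  if (length(un) > 0) {
    ord <- un[order(long$mz[un])]
    mzs <- long$mz[ord]
    gap_ppm <- diff(mzs) / mzs[-length(mzs)] * 1e6
    cluster <- cumsum(c(1, as.integer(gap_ppm > tol_ppm)))
    rep_mz <- vapply(split(mzs, cluster), stats::median, numeric(1))
    long$feature[ord] <- sprintf("mz_%.5f", rep_mz[cluster])
  }

  # same-spectrum collisions within a feature: keep the higher intensity
  key <- paste(long$feature, long$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_coll <- sum(duplicated(key))
    vdom_log("align_peaks: %d same-spectrum collisions, keeping max intensity",
             n_coll)
    long <- long[order(key, -long$intensity), , drop = FALSE]
    long <- long[!duplicated(paste(long$feature, long$sample_id, sep = "\r")), ,
                 drop = FALSE]
  }

  feats <- sort(unique(long$feature))
  intensity <- matrix(0, nrow = length(feats), ncol = length(ids),
                      dimnames = list(feats, ids))
  snr <- intensity
  ridx <- match(long$feature, feats)
  cidx <- match(long$sample_id, ids)
  intensity[cbind(ridx, cidx)] <- long$intensity
  snr[cbind(ridx, cidx)] <- long$snr

  features <- data.frame(
    feature_id = feats,
    formula = ifelse(grepl("^mz_", feats), NA_character_, feats),
    stringsAsFactors = FALSE
  )
  fmz <- rep(NA_real_, nrow(features))
  is_mz <- grepl("^mz_", feats)
  fmz[is_mz] <- as.numeric(sub("^mz_", "", feats[is_mz]))
  fmz[!is_mz] <- formula_to_mz(feats[!is_mz])
  features$mz <- fmz

  det_limit <- apply(intensity, 2, function(col) min(col[col > 0]))
  vdom_log("align_peaks: %d features across %d spectra",
           length(feats), length(ids))
  structure(list(intensity = intensity, snr = snr, features = features,
                 meta = meta, detection_limit = det_limit),
            class = "aligned_peaks")
}

#' @export
print.aligned_peaks <- function(x, ...) {
  cat(sprintf("aligned_peaks: %d features x %d spectra (%d blanks)\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$meta$is_blank)))
  invisible(x)
}

.drop_features <- function(m, drop) {
  m$intensity <- m$intensity[!drop, , drop = FALSE]
  m$snr <- m$snr[!drop, , drop = FALSE]
  m$features <- m$features[!drop, , drop = FALSE]
  m
}

#' Minimum-occurrence filter
#'
#' Removes features detected in fewer than `k` non-blank spectra of the
#' whole dataset ("detected at least 3 times"), discarding analytical
#' noise and non-reproducible peaks. Blanks do not count towards the
#' occurrence.
#'
#' @param m an `aligned_peaks` object.
#' @param k minimum number of non-blank detections (inclusive).
#' @return filtered `aligned_peaks`.
#' @export
min_occurrence_filter <- function(m, k = 3) {
  stopifnot(inherits(m, "aligned_peaks"), k >= 1)
  study <- !m$meta$is_blank
  occ <- rowSums(m$intensity[, study, drop = FALSE] > 0)
  drop <- occ < k
  vdom_log("min_occurrence_filter: removed %d of %d features (k = %d)",
           sum(drop), length(drop), k)
  .drop_features(m, drop)
}

#' Raise the per-spectrum detection limit
#'
#' Multiplies each spectrum's recorded detection limit (its minimum
#' detected intensity at alignment time) by `factor` and sets entries
#' below the raised floor to not-detected. This accounts for slight
#' differences in detection limit between individual spectra. Because the
#' original limit is stored on the matrix rather than recomputed, the
#' operation is idempotent.
#'
#' @param m an `aligned_peaks` object.
#' @param factor multiplicative raise, >= 1 (default 1.05, i.e. +5%).
#' @return filtered `aligned_peaks`.
#' @export
raise_detection_limit <- function(m, factor = 1.05) {
  stopifnot(inherits(m, "aligned_peaks"))
  if (factor < 1) stop("detection limit factor must be >= 1")
  removed <- 0L
  had_signal <- colSums(m$intensity > 0) > 0
  for (j in seq_len(ncol(m$intensity))) {
    floor_j <- m$detection_limit[j] * factor
    cut <- m$intensity[, j] > 0 & m$intensity[, j] < floor_j
    removed <- removed + sum(cut)
    m$intensity[cut, j] <- 0
    m$snr[cut, j] <- 0
  }
  emptied <- had_signal & colSums(m$intensity > 0) == 0
  if (any(emptied)) {
    warning("raise_detection_limit emptied spectra: ",
            paste(colnames(m$intensity)[emptied], collapse = ", "))
  }
  vdom_log("raise_detection_limit: removed %d entries (factor %.3f)",
           removed, factor)
  m
}

#' Blank-based contaminant removal
#'
#' Removes a feature from the entire dataset when the maximum
#' signal-to-noise ratio observed in the blanks exceeds `ratio` times its
#' maximum S/N in the study samples, or when it is detected in at least
#' `blank_majority` blank spectra. Blank columns are dropped from the
#' matrix afterwards.
#'
#' @param m an `aligned_peaks` object.
#' @param ratio blank-to-sample S/N ratio threshold (default 20).
#' @param blank_majority minimum number of blank detections (default 7).
#' @return filtered `aligned_peaks` without blank columns.
#' @export
blank_filter <- function(m, ratio = 20, blank_majority = 7) {
  stopifnot(inherits(m, "aligned_peaks"))
  blanks <- m$meta$is_blank
  if (!any(blanks)) {
    warning("no blank spectra present; blank_filter is a no-op")
    return(m)
  }
  bsnr <- apply(m$snr[, blanks, drop = FALSE], 1, max)
  ssnr <- apply(m$snr[, !blanks, drop = FALSE], 1, max)
  n_blank_det <- rowSums(m$intensity[, blanks, drop = FALSE] > 0)
  drop <- (bsnr > ratio * ssnr) | (n_blank_det >= blank_majority)
  vdom_log("blank_filter: removed %d of %d features (%d by %gx S/N, %d by >=%d blanks)",
           sum(drop), length(drop), sum(bsnr > ratio * ssnr),
           ratio, sum(n_blank_det >= blank_majority), blank_majority)
  m <- .drop_features(m, drop)
  m$intensity <- m$intensity[, !blanks, drop = FALSE]
  m$snr <- m$snr[, !blanks, drop = FALSE]
  m$detection_limit <- m$detection_limit[!blanks]
  m$meta <- m$meta[!blanks, , drop = FALSE]
  m
}

#' Flag analytical replicate outliers
#'
#' Either removes a configured list of spectrum ids (`manual` mode,
#' mirroring manual curation of obvious outliers) or flags replicates
#' whose Bray-Curtis dissimilarity to their replicate-group mean profile
#' exceeds `threshold` (`distance` mode).
#'
#' @param m an `aligned_peaks` object (blanks may be present; they are
#'   never flagged).
#' @param method `"manual"` or `"distance"`.
#' @param ids spectrum ids to remove in manual mode.
#' @param threshold Bray-Curtis dissimilarity threshold in distance mode.
#' @return character vector of flagged spectrum ids.
#' @export
flag_replicate_outliers <- function(m, method = c("manual", "distance"),
                                    ids = character(0), threshold = 0.5) {
  stopifnot(inherits(m, "aligned_peaks"))
  method <- match.arg(method)
  meta <- m$meta[!m$meta$is_blank, , drop = FALSE]
  if (method == "manual") {
    unknown <- setdiff(ids, colnames(m$intensity))
    if (length(unknown) > 0) {
      stop("unknown spectrum id(s): ", paste(unknown, collapse = ", "))
    }
    flagged <- intersect(ids, meta$sample_id)
  } else {
    flagged <- character(0)
    groups <- split(meta$sample_id, paste(meta$depth, meta$arm, meta$day))
    for (g in groups) {
      if (length(g) < 2) next
      sub <- m$intensity[, g, drop = FALSE]
      centre <- rowMeans(sub)
      d <- vapply(g, function(id) {
        bray_curtis(sub[, id], centre)
      }, numeric(1))
      flagged <- c(flagged, g[d > threshold])
    }
  }
  # never allow a whole replicate group to disappear
  keep_meta <- meta[!(meta$sample_id %in% flagged), , drop = FALSE]
  gone <- setdiff(paste(meta$depth, meta$arm, meta$day),
                  paste(keep_meta$depth, keep_meta$arm, keep_meta$day))
  if (length(gone) > 0) {
    stop("outlier removal would drop all replicates of: ",
         paste(gone, collapse = "; "))
  }
  vdom_log("flag_replicate_outliers(%s): flagged %d spectra",
           method, length(flagged))
  flagged
}

#' Remove flagged spectra from an aligned matrix
#'
#' @param m an `aligned_peaks` object.
#' @param ids spectrum ids to drop.
#' @return `aligned_peaks` without the given columns.
#' @export
drop_spectra <- function(m, ids) {
  stopifnot(inherits(m, "aligned_peaks"))
  keep <- !(colnames(m$intensity) %in% ids)
  m$intensity <- m$intensity[, keep, drop = FALSE]
  m$snr <- m$snr[, keep, drop = FALSE]
  m$detection_limit <- m$detection_limit[keep]
  m$meta <- m$meta[keep, , drop = FALSE]
  m
}

#' Normalize to sum intensity
#'
#' Keeps only features with an assigned molecular formula (unassigned
#' features are returned in the `unassigned` attribute) and divides each
#' spectrum's intensities by its total remaining intensity, so every
#' spectrum sums to 1.
#'
#' @param m an `aligned_peaks` object after all filters.
#' @return `formula_table`: formulas x spectra matrix with attributes
#'   `normalized` (TRUE), `meta`, and `unassigned` (the unassigned
#'   feature intensities).
#' @export
normalize_intensities <- function(m) {
  stopifnot(inherits(m, "aligned_peaks"))
  has_formula <- !is.na(m$features$formula)
  tab <- m$intensity[has_formula, , drop = FALSE]
  rownames(tab) <- m$features$formula[has_formula]
  totals <- colSums(tab)
  empty <- which(totals == 0)
  if (length(empty) > 0) {
    stop("no assigned intensity left after QC in spectrum: ",
         paste(colnames(tab)[empty], collapse = ", "))
  }
  tab <- sweep(tab, 2, totals, "/")
  vdom_log("normalize_intensities: %d assigned features, %d unassigned reported separately",
           sum(has_formula), sum(!has_formula))
  structure(tab,
            normalized = TRUE,
            meta = m$meta,
            unassigned = m$intensity[!has_formula, , drop = FALSE],
            class = c("formula_table", "matrix"))
}

#' Run the full quality-control pipeline
#'
#' Fixed order: S/N threshold (at assignment) -> alignment -> raised
#' detection limit -> minimum occurrence -> blank removal -> replicate
#' outliers -> normalization.
#'
#' @param assigned named list of assigned spectra.
#' @param meta sample metadata.
#' @param tol_ppm alignment tolerance (ppm).
#' @param min_occurrence minimum non-blank detections.
#' @param detection_limit_factor detection limit raise factor.
#' @param blank_snr_ratio blank 20x S/N rule threshold.
#' @param blank_majority blank majority rule count.
#' @param outlier_ids manually flagged replicate outliers.
#' @return list with `table` (normalized `formula_table`), `outliers`,
#'   and `report` (feature counts per stage).
#' @export
qc_pipeline <- function(assigned, meta, tol_ppm = 0.5,
                        min_occurrence = 3, detection_limit_factor = 1.05,
                        blank_snr_ratio = 20, blank_majority = 7,
                        outlier_ids = character(0)) {
  m <- align_peaks(assigned, meta, tol_ppm = tol_ppm)
  report <- data.frame(stage = "aligned", n_features = nrow(m$intensity),
                       n_spectra = ncol(m$intensity))
  m <- raise_detection_limit(m, factor = detection_limit_factor)
  report <- rbind(report, data.frame(stage = "detection_limit",
                                     n_features = sum(rowSums(m$intensity > 0) > 0),
                                     n_spectra = ncol(m$intensity)))
  m <- min_occurrence_filter(m, k = min_occurrence)
  report <- rbind(report, data.frame(stage = "min_occurrence",
                                     n_features = nrow(m$intensity),
                                     n_spectra = ncol(m$intensity)))
  m <- blank_filter(m, ratio = blank_snr_ratio,
                    blank_majority = blank_majority)
  report <- rbind(report, data.frame(stage = "blank_filter",
                                     n_features = nrow(m$intensity),
                                     n_spectra = ncol(m$intensity)))
  outliers <- flag_replicate_outliers(m, method = "manual", ids = outlier_ids)
  if (length(outliers) > 0) m <- drop_spectra(m, outliers)
  table <- normalize_intensities(m)
  report <- rbind(report, data.frame(stage = "normalized",
                                     n_features = nrow(table),
                                     n_spectra = ncol(table)))
  list(table = table, outliers = outliers, report = report)
}
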