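#' Designed incubation time points (days)
#' @export
DESIGN_DAYS <- c(0L, 6L, 14L, 55L)

#' Analytical mass window (Da)
#'
#' Only peaks with m/z inside this window enter the pipeline; the window
#' is enforced at read time so unassigned-peak statistics respect it too.
#' @export
MASS_WINDOW <- c(92.1, 2000)

.read_delim_checked <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = delim, header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a peak list
#'
#' Reads one spectrum from delimited text with mandatory header columns
#' `mz`, `intensity`, `snr`. Rows outside the analytical mass window are
#' dropped (count logged); remaining peaks are sorted by ascending m/z.
#'
#' @param path file path.
#' @param delim field delimiter (tab default; comma accepted).
#' @param mass_window numeric length-2 inclusive m/z window in Da.
#' @param sample_id identifier attached to the spectrum; defaults to the
#'   file name without extension.
#' @return data frame with columns `mz`, `intensity`, `snr` and attribute
#'   `sample_id`.
#' @export
read_peaklist <- function(path, delim = "\t", mass_window = MASS_WINDOW,
                          sample_id = NULL) {
  df <- .read_delim_checked(path, delim)
  need <- c("mz", "intensity", "snr")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("peak list ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[need]
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop("non-numeric or missing '", col, "' in ", path,
           " at data line ", bad[1])
    }
    df[[col]] <- v
  }
  bad <- which(df$intensity <= 0)
  if (length(bad) > 0) {
    stop("non-positive intensity in ", path, " at data line ", bad[1])
  }
  bad <- which(df$snr <= 0)
  if (length(bad) > 0) {
    stop("non-positive snr in ", path, " at data line ", bad[1])
  }
  inside <- df$mz >= mass_window[1] & df$mz <= mass_window[2]
  if (any(!inside)) {
    vdom_log("read_peaklist(%s): dropped %d of %d peaks outside [%g, %g] Da",
             basename(path), sum(!inside), nrow(df),
             mass_window[1], mass_window[2])
  }
  df <- df[inside, , drop = FALSE]
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  attr(df, "sample_id") <- sample_id
  df
}

#' Write a peak list
#'
#' @param spectrum data frame with columns `mz`, `intensity`, `snr`.
#' @param path output file path.
#' @param delim field delimiter.
#' @export
write_peaklist <- function(spectrum, path, delim = "\t") {
  df <- as.data.frame(spectrum)[c("mz", "intensity", "snr")]
  df$mz <- formatC(df$mz, digits = 12, format = "g")
  df$intensity <- formatC(df$intensity, digits = 12, format = "g")
  df$snr <- formatC(df$snr, digits = 12, format = "g")
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Expects columns `sample_id`, `depth`, `arm`, `day`, `replicate`. Arms
#' are `treatment`, `control` or `blank`; depths `surface` or
#' `subsurface` (ignored for blanks); days must be designed time points
#' unless `allow_free_days` is set. The (depth, arm, day, replicate)
#' combination must be unique among study samples.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @param allow_free_days allow days outside [DESIGN_DAYS].
#' @return data frame with columns `sample_id`, `depth`, `arm`, `day`,
#'   `replicate`, `is_blank`.
#' @export
read_sample_table <- function(path, delim = "\t", allow_free_days = FALSE) {
  df <- .read_delim_checked(path, delim)
  need <- c("sample_id", "depth", "arm", "day", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[need]
  validate_sample_meta(df, allow_free_days = allow_free_days)
}

#' Validate sample metadata
#'
#' @param df data frame with columns `sample_id`, `depth`, `arm`, `day`,
#'   `replicate`.
#' @param allow_free_days allow days outside [DESIGN_DAYS].
#' @return the validated data frame with an added `is_blank` column.
#' @export
validate_sample_meta <- function(df, allow_free_days = FALSE) {
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  bad_arm <- setdiff(unique(df$arm), c("treatment", "control", "blank"))
  if (length(bad_arm) > 0) stop("unknown arm value: ", bad_arm[1])
  df$is_blank <- df$arm == "blank"
  study <- df[!df$is_blank, , drop = FALSE]
  bad_depth <- setdiff(unique(study$depth), c("surface", "subsurface"))
  if (length(bad_depth) > 0) stop("unknown depth label: ", bad_depth[1])
  study$day <- suppressWarnings(as.integer(study$day))
  if (anyNA(study$day)) stop("non-integer day for a study sample")
  if (!allow_free_days) {
    off <- setdiff(unique(study$day), DESIGN_DAYS)
    if (length(off) > 0) {
      stop("day ", off[1], " is not a designed time point (",
           paste(DESIGN_DAYS, collapse = ", "),
           "); set allow_free_days = TRUE to accept it")
    }
  }
  if (any(suppressWarnings(as.integer(study$replicate)) < 1, na.rm = TRUE) ||
      anyNA(suppressWarnings(as.integer(study$replicate)))) {
    stop("replicate must be an integer >= 1")
  }
  key <- paste(study$depth, study$arm, study$day, study$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (depth, arm, day, replicate): ", key[duplicated(key)][1])
  }
  df$day <- suppressWarnings(as.integer(df$day))
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  vdom_log("sample table: %d study samples, %d blanks",
           sum(!df$is_blank), sum(df$is_blank))
  df
}

#' Write a formula table
#'
#' Writes a formulas x samples matrix as delimited text: first column
#' `formula` (Hill strings), one column per sample, values printed at 12
#' significant digits. A leading comment line records the normalization
#' flag so [read_formula_table()] restores it.
#'
#' @param table formula table (matrix with Hill-string rownames and
#'   attribute `normalized`).
#' @param path output file path.
#' @param delim field delimiter.
#' @export
write_formula_table <- function(table, path, delim = "\t") {
  m <- as.matrix(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized: %s",
                     isTRUE(attr(table, "normalized"))), con)
  header <- paste(c("formula", colnames(m)), collapse = delim)
  writeLines(header, con)
  if (nrow(m) > 0) {
    vals <- matrix(formatC(m, digits = 12, format = "g"), nrow = nrow(m))
    lines <- apply(cbind(rownames(m), vals), 1, paste, collapse = delim)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a formula table
#'
#' Inverse of [write_formula_table()].
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return formulas x samples numeric matrix with attribute `normalized`.
#' @export
read_formula_table <- function(path, delim = "\t") {
  first <- readLines(path, n = 1)
  normalized <- grepl("normalized: TRUE", first, fixed = TRUE)
  df <- read.delim(path, sep = delim, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "formula") stop("first column must be 'formula'")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$formula
  structure(m, normalized = normalized, class = c("formula_table", "matrix"))
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration and merges it over the package defaults:
#' every tolerance and threshold used by the pipeline is a named key whose
#' default is the value applied in the original workflow.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    delim = "\t",
    mass_window = MASS_WINDOW,
    tolerance_ppm = 0.5,
    min_snr = 4,
    min_occurrence = 3,
    detection_limit_factor = 1.05,
    blank_snr_ratio = 20,
    blank_majority = 7,
    presence_rule = "all_replicates",
    n_perm = 9999,
    spearman_alpha = 0.001,
    rarefaction_depth = 11000,
    rarefaction_boots = 30,
    others_threshold = 0.01
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
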