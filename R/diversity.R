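#' Rarefaction-based diversity indices
#'
#' Repeatedly rarefies each sample to a common read depth (subsampling
#' without replacement) and computes OTU richness, Shannon diversity
#' (natural log) and Pielou's evenness `J = H / ln(richness)` per
#' bootstrap, reporting the mean and standard deviation over bootstraps.
#' Samples with fewer reads than `depth` are skipped with a warning.
#' `J` is 0 by convention when the rarefied sample holds a single OTU.
#'
#' @param counts OTUs x samples matrix of non-negative integer read
#'   counts.
#' @param depth rarefaction depth (default 11000 reads).
#' @param boots number of bootstrap rarefactions (default 30).
#' @param seed RNG seed.
#' @return data frame per retained sample: `sample`, `richness_mean`,
#'   `richness_sd`, `shannon_mean`, `shannon_sd`, `pielou_mean`,
#'   `pielou_sd`.
#' @export
rarefy_bootstrap <- function(counts, depth = 11000, boots = 30, seed = 1) {
  if (depth < 1) stop("rarefaction depth must be >= 1")
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  totals <- colSums(m)
  keep <- totals >= depth
  if (!all(keep)) {
    warning("skipping sample(s) below rarefaction depth: ",
            paste(colnames(m)[!keep], collapse = ", "))
  }
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) stop("no sample reaches the rarefaction depth")
  samples <- colnames(m)
  with_seed(seed, {
    rich <- shan <- piel <- matrix(NA_real_, nrow = boots, ncol = ncol(m))
    for (b in seq_len(boots)) {
      # rrarefy's "observed counts" heuristic misfires on abundant
      # synthetic communities; depth feasibility is checked above
      rar <- suppressWarnings(vegan::rrarefy(t(m), sample = depth))
      r <- rowSums(rar > 0)
      h <- vegan::diversity(rar, index = "shannon")
      j <- ifelse(r > 1, h / log(r), 0)
      rich[b, ] <- r
      shan[b, ] <- h
      piel[b, ] <- j
    }
    data.frame(
      sample = samples,
      richness_mean = colMeans(rich), richness_sd = apply(rich, 2, sd),
      shannon_mean = colMeans(shan), shannon_sd = apply(shan, 2, sd),
      pielou_mean = colMeans(piel), pielou_sd = apply(piel, 2, sd),
      row.names = NULL
    )
  })
}

#' Aggregate rare taxa into "Others"
#'
#' Collapses OTU counts to taxonomy labels and merges taxa whose relative
#' abundance stays below `threshold` in every sample of the experiment
#' into a single "Others" group. Returns relative abundances (columns sum
#' to 1).
#'
#' @param counts OTUs x samples count matrix.
#' @param taxonomy character vector of taxon labels, one per OTU row.
#' @param threshold relative-abundance cutoff (default 0.01, i.e. 1%).
#' @return taxa x samples relative-abundance matrix.
#' @export
aggregate_others <- function(counts, taxonomy, threshold = 0.01) {
  m <- as.matrix(counts)
  stopifnot(length(taxonomy) == nrow(m))
  agg <- rowsum(m, group = taxonomy)
  rel <- sweep(agg, 2, colSums(agg), "/")
  rare <- apply(rel, 1, max) < threshold
  if (any(rare)) {
    others <- colSums(rel[rare, , drop = FALSE])
    rel <- rbind(rel[!rare, , drop = FALSE], Others = others)
  }
  rel
}

#' Virus-to-microbial-cell ratio
#'
#' @param vlp virus-like particle concentration (counts per mL).
#' @param tcc total cell count (counts per mL), > 0.
#' @return ratio `vlp / tcc` (vectorised).
#' @export
virus_to_cell_ratio <- function(vlp, tcc) {
  if (any(tcc <= 0)) stop("total cell count must be positive")
  if (any(vlp < 0)) stop("VLP count must be non-negative")
  vlp / tcc
}
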