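#' Hellinger transform
#'
#' Square root of relative abundances: each entry becomes
#' `sqrt(value / row sum)`, so the squared entries of a row sum to 1.
#' Makes Euclidean-embedding methods well behaved on compositional data.
#' A `formula_table` (formulas x samples) is transposed internally so the
#' result is always samples x features.
#'
#' @param x non-negative samples x features matrix, or a `formula_table`.
#' @return transformed samples x features matrix.
#' @export
hellinger <- function(x) {
  if (inherits(x, "formula_table")) x <- t(unclass(x))
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative values in abundance matrix")
  rs <- rowSums(x)
  if (any(rs == 0)) stop("all-zero row in abundance matrix")
  vegan::decostand(x, method = "hellinger")
}

#' Bray-Curtis dissimilarity between two vectors
#'
#' `sum(|a - b|) / sum(a + b)`, in \[0, 1\].
#'
#' @param a,b non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return scalar dissimilarity.
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  if (sum(a) + sum(b) == 0) stop("both vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param x samples x features non-negative matrix (e.g. Hellinger
#'   transformed relative intensities), or a `formula_table`.
#' @return `dist` object of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis_matrix <- function(x) {
  if (inherits(x, "formula_table")) x <- t(unclass(x))
  vegan::vegdist(as.matrix(x), method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower
#' double-centering of -D^2/2 and eigendecomposition, with scores scaled
#' by the square roots of the positive eigenvalues. Negative eigenvalues
#' are reported unchanged (no correction); explained fractions are
#' computed over positive eigenvalues only.
#'
#' @param d `dist` object or symmetric zero-diagonal matrix.
#' @param k number of axes to return (default 2).
#' @return list of class `pcoa_ordination`: `scores` (samples x k,
#'   columns centred), `eigenvalues` (all, decreasing),
#'   `explained_fraction` (per returned axis).
#' @export
pcoa <- function(d, k = 2) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m), tol = 1e-8)) {
      stop("dissimilarity matrix must be symmetric")
    }
    if (any(abs(diag(m)) > 1e-12)) stop("dissimilarity diagonal must be zero")
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  k <- min(k, n - 1)
  sc <- cmdscale(d, k = k, eig = TRUE)
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- sum(eig[eig > 0])
  scores <- sc$points
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(
    scores = scores,
    eigenvalues = eig,
    explained_fraction = eig[seq_len(ncol(scores))] / pos
  ), class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, axis variance %s\n", nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction),
                    collapse = ", ")))
  invisible(x)
}

# r2 of regressing y on centred score axes; X is the centred score matrix.
.vector_r2 <- function(scores_c, y) {
  y <- y - mean(y)
  ss_tot <- sum(y^2)
  if (ss_tot == 0) return(NA_real_)
  beta <- solve(crossprod(scores_c), crossprod(scores_c, y))
  ss_fit <- sum((scores_c %*% beta)^2)
  ss_fit / ss_tot
}

#' Permutation fitting of environmental vectors to ordination scores
#'
#' For each environmental variable, regresses the variable on the first
#' two ordination axes; the squared multiple correlation r2 measures how
#' much of the variable tracks the ordination, and its significance is
#' assessed by permuting sample labels. The p-value convention
#' `(1 + #{permuted r2 >= observed}) / (n_perm + 1)` never returns zero.
#' Constant variables get `NA` r2 and p.
#'
#' @param ordination a `pcoa_ordination`.
#' @param env samples x variables numeric data frame or matrix; rows must
#'   match the ordination samples (by rowname when present, else order).
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed.
#' @return data frame with one row per variable: `variable`, direction
#'   cosines `axis1`/`axis2` (unit length), `r2`, `p_perm`.
#' @export
fit_env_vectors <- function(ordination, env, n_perm = 9999, seed = 1) {
  stopifnot(inherits(ordination, "pcoa_ordination"), n_perm >= 1)
  scores <- ordination$scores[, 1:2, drop = FALSE]
  env <- as.data.frame(env)
  if (!is.null(rownames(scores)) && !is.null(rownames(env)) &&
      all(rownames(scores) %in% rownames(env))) {
    env <- env[rownames(scores), , drop = FALSE]
  }
  if (nrow(env) != nrow(scores)) {
    stop("env rows do not match ordination samples")
  }
  scores_c <- sweep(scores, 2, colMeans(scores))
  n <- nrow(scores_c)
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    out <- lapply(names(env), function(v) {
      y <- as.numeric(env[[v]])
      if (anyNA(y)) stop("missing values in environmental variable ", v)
      if (stats::var(y) == 0) {
        return(data.frame(variable = v, axis1 = NA_real_, axis2 = NA_real_,
                          r2 = NA_real_, p_perm = NA_real_))
      }
      r2_obs <- .vector_r2(scores_c, y)
      beta <- solve(crossprod(scores_c), crossprod(scores_c, y - mean(y)))
      dir <- as.numeric(beta) / sqrt(sum(beta^2))
      r2_perm <- vapply(seq_len(n_perm), function(i) {
        .vector_r2(scores_c, y[perms[, i]])
      }, numeric(1))
      p <- (1 + sum(r2_perm >= r2_obs)) / (n_perm + 1)
      data.frame(variable = v, axis1 = dir[1], axis2 = dir[2],
                 r2 = r2_obs, p_perm = p)
    })
    do.call(rbind, out)
  })
}

#' Permutation Spearman screening of single formulas
#'
#' Spearman rank correlation between each formula's relative intensities
#' and each environmental parameter, with a permutation p-value
#' (`(1 + #{|rho_perm| >= |rho|}) / (n_perm + 1)`). Ties are handled by
#' average ranks. Only pairs with `p_perm < alpha` are returned unless
#' `alpha` is `NULL`.
#'
#' @param table `formula_table` (formulas x samples) or samples x
#'   features matrix.
#' @param env samples x variables data frame or matrix.
#' @param n_perm number of permutations (default 9999).
#' @param alpha raw p-value cutoff (default 0.001; `NULL` keeps all
#'   pairs). No multiple-testing correction is applied.
#' @param seed RNG seed.
#' @return data frame with columns `formula`, `variable`, `rho`,
#'   `p_perm`.
#' @export
spearman_screen <- function(table, env, n_perm = 9999, alpha = 0.001,
                            seed = 1) {
  x <- if (inherits(table, "formula_table")) t(unclass(table)) else
    as.matrix(table)
  env <- as.data.frame(env)
  if (!is.null(rownames(x)) && !is.null(rownames(env)) &&
      all(rownames(x) %in% rownames(env))) {
    env <- env[rownames(x), , drop = FALSE]
  }
  if (nrow(env) != nrow(x)) stop("env rows do not match samples")
  n <- nrow(x)
  if (n < 3) stop("fewer than 3 samples")
  rx <- apply(x, 2, rank)  # average ranks for ties
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    out <- lapply(names(env), function(v) {
      y <- as.numeric(env[[v]])
      ry <- rank(y)
      if (stats::var(ry) == 0) return(NULL)
      rho <- suppressWarnings(cor(rx, ry))[, 1]
      ry_perm <- matrix(ry[perms], nrow = n)
      rho_perm <- suppressWarnings(cor(rx, ry_perm))
      exceed <- abs(rho_perm) >= abs(rho) - 1e-12
      p <- (1 + rowSums(exceed, na.rm = TRUE)) / (n_perm + 1)
      data.frame(formula = colnames(x), variable = v, rho = rho,
                 p_perm = p, row.names = NULL)
    })
    res <- do.call(rbind, out)
    if (!is.null(alpha)) res <- res[!is.na(res$p_perm) & res$p_perm < alpha, ,
                                    drop = FALSE]
    rownames(res) <- NULL
    res
  })
}
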