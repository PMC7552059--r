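test_that("Hellinger transform takes square roots of relative abundance", {
  got <- hellinger(matrix(c(4, 1), nrow = 1))
  expect_equal(as.numeric(got), c(sqrt(0.8), sqrt(0.2)))
  got2 <- hellinger(matrix(c(1, 0, 0), nrow = 1))
  expect_equal(as.numeric(got2), c(1, 0, 0))
  # zeros stay zeros; squared rows sum to 1
  set.seed(3)
  x <- matrix(rpois(60, 3), nrow = 6)
  h <- hellinger(x)
  expect_equal(h == 0, x == 0)
  expect_equal(rowSums(h^2), rep(1, 6))
  expect_error(hellinger(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("Bray-Curtis matches its definition and metric properties", {
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 2), c(2, 2)), 0)
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 / 3)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(10); b <- runif(10)
    d <- bray_curtis(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(b, a))
  }
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("PCoA on Euclidean distances reproduces the configuration", {
  set.seed(11)
  pts <- matrix(rnorm(8), ncol = 2)
  d <- dist(pts)
  ord <- pcoa(d, k = 2)
  expect_lt(max(abs(dist(ord$scores) - d)), 1e-8)
  expect_equal(colMeans(ord$scores), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-12)
  # identical samples land on identical scores
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 1, 0))
  ord2 <- pcoa(dist(x), k = 2)
  expect_lt(max(abs(ord2$scores["a", ] - ord2$scores["b", ])), 1e-6)
  # collinear 1-D points: a single positive axis explains everything
  ord3 <- pcoa(dist(matrix(c(0, 1, 2), ncol = 1)), k = 2)
  expect_equal(sum(ord3$eigenvalues > 1e-10), 1)
  expect_equal(ord3$explained_fraction[1], 1, tolerance = 1e-10)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("a variable linear in axis 1 fits perfectly", {
  set.seed(5)
  pts <- matrix(rnorm(24), ncol = 2)
  ord <- pcoa(dist(pts), k = 2)
  env <- data.frame(linear = 2 * ord$scores[, 1] + 1,
                    noise = rnorm(12))
  fit <- fit_env_vectors(ord, env, n_perm = 199, seed = 9)
  expect_equal(fit$r2[fit$variable == "linear"], 1, tolerance = 1e-9)
  expect_equal(fit$p_perm[fit$variable == "linear"], 1 / 200)
  expect_equal(sum(fit$axis1^2 + fit$axis2^2), 2, tolerance = 1e-9)
  # same seed, same p-values; constant variables are reported missing
  fit2 <- fit_env_vectors(ord, env, n_perm = 199, seed = 9)
  expect_identical(fit$p_perm, fit2$p_perm)
  fit3 <- fit_env_vectors(ord, data.frame(const = rep(1, 12)),
                          n_perm = 99, seed = 1)
  expect_true(is.na(fit3$r2))
})

test_that("vector fitting agrees with vegan envfit", {
  set.seed(21)
  x <- matrix(rlnorm(20 * 30), nrow = 20)
  d <- bray_curtis_matrix(hellinger(x))
  ord <- pcoa(d, k = 2)
  env <- data.frame(v1 = rnorm(20), v2 = ord$scores[, 1] + rnorm(20, 0, .3))
  fit <- fit_env_vectors(ord, env, n_perm = 499, seed = 3)
  ef <- vegan::envfit(ord$scores[, 1:2], env, permutations = 499)
  expect_equal(fit$r2, unname(ef$vectors$r), tolerance = 1e-8)
  expect_equal(abs(fit$axis1), abs(unname(ef$vectors$arrows[, 1])),
               tolerance = 1e-6)
})

test_that("Spearman screening finds perfect monotone relations", {
  tab <- matrix(0, nrow = 2, ncol = 8,
                dimnames = list(c("C6H12O6", "C7H6O2"), paste0("s", 1:8)))
  tab["C6H12O6", ] <- c(1, 2, 3, 4, 5, 6, 7, 8) / 36
  tab["C7H6O2", ] <- rev(tab["C6H12O6", ])
  ft <- structure(tab, normalized = TRUE,
                  class = c("formula_table", "matrix"))
  env <- data.frame(DOC = 1:8, row.names = paste0("s", 1:8))
  got <- spearman_screen(ft, env, n_perm = 199, alpha = NULL, seed = 2)
  expect_equal(got$rho[got$formula == "C6H12O6"], 1)
  expect_equal(got$rho[got$formula == "C7H6O2"], -1)
  # the permutation p floor is (1 + 0) / (n_perm + 1)
  expect_equal(min(got$p_perm), 1 / 200)
  expect_identical(got, spearman_screen(ft, env, n_perm = 199,
                                        alpha = NULL, seed = 2))
  expect_error(spearman_screen(ft[, 1:2], env[1:2, , drop = FALSE],
                               n_perm = 99), "3 samples")
})

test_that("the alpha cutoff filters the screening output", {
  set.seed(8)
  tab <- matrix(runif(5 * 10), nrow = 5,
                dimnames = list(paste0("C", 10:14, "H20O5"),
                                paste0("s", 1:10)))
  ft <- structure(tab, normalized = TRUE,
                  class = c("formula_table", "matrix"))
  env <- data.frame(DOC = rnorm(10), row.names = paste0("s", 1:10))
  all_rows <- spearman_screen(ft, env, n_perm = 99, alpha = NULL, seed = 1)
  expect_equal(nrow(all_rows), 5)
  few <- spearman_screen(ft, env, n_perm = 99, alpha = 0.001, seed = 1)
  expect_true(all(few$p_perm < 0.001))
})
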