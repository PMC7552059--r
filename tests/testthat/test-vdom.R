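make_table <- function(values, ids, meta) {
  structure(values, normalized = TRUE, meta = meta,
            class = c("formula_table", "matrix"))
}

test_that("presence requires detection in every replicate by default", {
  ids <- paste0("t6r", 1:3)
  meta <- make_meta(ids, day = 6)
  tab <- make_table(rbind(C6H12O6 = c(0.1, 0.2, 0.3),
                          C7H6O2 = c(0.1, 0, 0.3)), ids, meta)
  colnames(tab) <- ids
  expect_equal(presence_set(tab, "subsurface", "treatment", 6), "C6H12O6")
  expect_setequal(presence_set(tab, "subsurface", "treatment", 6,
                               rule = "any_replicate"),
                  c("C6H12O6", "C7H6O2"))
  expect_error(presence_set(tab, "surface", "treatment", 6), "condition")
})

test_that("vdom detection is pure set arithmetic on presence sets", {
  got <- detect_vdom(c("A", "B", "C"), "B", "C", character(0))
  expect_equal(got, "A")
  expect_length(detect_vdom(c("B", "C"), "B", "C", character(0)), 0)
  # output disjoint from all exclusion sets over random cases
  set.seed(2)
  for (i in 1:20) {
    u <- paste0("f", 1:40)
    t6 <- sample(u, 20); c6 <- sample(u, 15)
    t0 <- sample(u, 15); c0 <- sample(u, 15)
    v <- detect_vdom(t6, c6, t0, c0)
    expect_length(intersect(v, union(c6, union(t0, c0))), 0)
    expect_true(all(v %in% t6))
  }
})

test_that("vdom fate reports persistence, removal and heteroatoms", {
  rep <- vdom_fate(c("C6H13NO2", "C6H12O6"), "C6H13NO2")
  expect_equal(rep$removed_fraction, 0.5)
  expect_equal(rep$persistent_set, "C6H13NO2")
  expect_equal(unname(rep$heteroatom_fractions["n"]), 0.5)
  all_p <- vdom_fate(c("C6H13O3P", "C7H15O3P"), character(0))
  expect_equal(unname(all_p$heteroatom_fractions["p"]), 1)
  expect_equal(all_p$removed_fraction, 1)
  empty <- vdom_fate(character(0), "C6H12O6")
  expect_true(is.na(empty$removed_fraction))
})

test_that("fraction of total matches simple ratios", {
  expect_equal(fraction_of_total(paste0("f", 1:16), paste0("f", 1:100)),
               0.16)
  expect_equal(fraction_of_total(character(0), "A"), 0)
  expect_equal(fraction_of_total("A", "A"), 1)
  expect_error(fraction_of_total("A", character(0)), "empty")
  expect_error(fraction_of_total("B", "A"), "subset")
})

test_that("vdom analysis recovers a hand-planted differential set", {
  days <- c(0, 6, 55)
  grid <- expand.grid(replicate = 1:2, day = days,
                      arm = c("treatment", "control"),
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s_d%d_r%d", grid$arm, grid$day, grid$replicate)
  meta <- make_meta(ids, day = grid$day, arm = grid$arm,
                    replicate = grid$replicate)
  formulas <- c("C10H16O5", "C11H22N2O4", "C12H20O6", "C9H18O4S")
  tab <- matrix(0.25, nrow = 4, ncol = length(ids),
                dimnames = list(formulas, ids))
  # C11H22N2O4: appears only in treatment from day 6 (true vdom, persists)
  tab["C11H22N2O4", grid$arm == "control" | grid$day == 0] <- 0
  # C9H18O4S: appears in treatment day 6 only (true vdom, removed by d55)
  tab["C9H18O4S", grid$arm == "control" | grid$day != 6] <- 0
  got <- vdom_analysis(make_table(tab, ids, meta), "subsurface",
                       day_final = 55)
  expect_setequal(got$vdom_set, c("C11H22N2O4", "C9H18O4S"))
  expect_equal(got$removed_fraction, 0.5)
  expect_equal(got$persistent_set, "C11H22N2O4")
  expect_equal(got$fraction_of_day6_total, 2 / 4)
})

test_that("van Krevelen coordinates use the all-replicates rule", {
  ids <- paste0("r", 1:3)
  meta <- make_meta(ids, day = 6)
  tab <- make_table(rbind(C6H12O6 = c(0.1, 0.2, 0.3),
                          C7H6O2 = c(0.5, 0, 0.5)), ids, meta)
  colnames(tab) <- ids
  vk <- vankrevelen_coords(tab, "subsurface", "treatment", 6)
  expect_equal(vk$formula, "C6H12O6")  # 2-of-3 replicate formula excluded
  expect_equal(vk$oc, 1)
  expect_equal(vk$hc, 2)
  expect_equal(vk$mean_rel_intensity, 0.2)
})
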