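make_family <- function(parent_lf = c(m = 2.0, f = 3.0), kid_lf = c(2.2, 2.6, 3.0),
                        habitat = "rural") {
  n <- length(kid_lf)
  ped <- validate_pedigree(data.frame(
    id = c("m", "f", paste0("k", seq_len(n))),
    sire = c(NA, NA, rep("m", n)),
    dam = c(NA, NA, rep("f", n)),
    sex = c("male", "female", rep("unknown", n)),
    habitat = habitat))
  phen <- tibble::tibble(
    id = ped$id,
    log_fid = c(parent_lf[["m"]], parent_lf[["f"]], kid_lf),
    fid_m = exp(log_fid), sex = ped$sex, habitat = ped$habitat, n_measures = 1L)
  list(ped = ped, phen = phen)
}

test_that("broods are averaged, filtered by measured parents, and immune to sib duplication", {
  fam <- make_family(kid_lf = c(1, 2, 6))
  ds <- build_po_dataset(fam$ped, fam$phen, "midparent")
  expect_equal(nrow(ds), 1)
  expect_equal(ds$offspring_value, 3)          # (1 + 2 + 6) / 3
  expect_equal(ds$parent_value, 2.5)           # (2 + 3) / 2
  expect_equal(ds$brood_size, 3L)

  # dam unmeasured: brood drops from midparent mode, survives father mode
  phen_nodam <- fam$phen[fam$phen$id != "f", ]
  expect_error(build_po_dataset(fam$ped, phen_nodam, "midparent"), "No broods")
  ds_f <- build_po_dataset(fam$ped, phen_nodam, "father")
  expect_equal(ds_f$parent_value, 2.0)

  # duplicating each offspring value within the brood changes nothing
  fam2 <- make_family(kid_lf = c(1, 2, 6, 1, 2, 6))
  ds2 <- build_po_dataset(fam2$ped, fam2$phen, "midparent")
  expect_equal(ds2$offspring_value, ds$offspring_value)
  expect_equal(ds2$parent_value, ds$parent_value)
})

test_that("OLS slope matches the closed-form normal equations", {
  # hand computation: Sxx = 5, Sxy = 3 -> b = 0.6; SSE = 0.2, s2 = 0.1,
  # se_b = sqrt(0.1 / 5)
  est <- ols_slope(c(0, 1, 2, 3), c(1, 2, 2, 3))
  expect_equal(est$b, 0.6)
  expect_equal(est$se_b, sqrt(0.02))
  exact <- suppressWarnings(ols_slope(1:4, 2 * (1:4)))  # lm flags the perfect fit
  expect_equal(exact$b, 2)
  expect_lt(exact$p, 1e-10)

  expect_error(ols_slope(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(ols_slope(1:2, 1:2), "3 points")

  # null calibration: with y independent of x the slope test is ~Uniform
  set.seed(77)
  pvals <- vapply(1:400, function(i) ols_slope(rnorm(50), rnorm(50))$p, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
  expect_lt(abs(mean(pvals) - 0.5), 0.06)
})

test_that("midparent h2 is the raw slope and is symmetric in the parents", {
  fam <- make_family()
  ped <- fam$ped; phen <- fam$phen
  # three families for a regression
  st <- simulate_fid_study(sim_config(n_founders = 60, n_generations = 2, seed = 3))
  ds <- build_po_dataset(st$pedigree, st$phenotypes, "midparent")
  est <- midparent_h2(ds)
  raw <- ols_slope(ds$parent_value, ds$offspring_value)
  expect_equal(est$h2, raw$b)
  expect_equal(est$se, raw$se_b)
  expect_true(is.na(est$correction_r))

  # swapping sire and dam phenotype values leaves the midparent value alone
  phen_swap <- st$phenotypes
  sires <- ds$sire; dams <- ds$dam   # monogamous design: one pair per parent
  i <- match(c(sires, dams), phen_swap$id)
  j <- match(c(dams, sires), st$phenotypes$id)
  phen_swap$log_fid[i] <- st$phenotypes$log_fid[j]
  ds_swap <- build_po_dataset(st$pedigree, phen_swap, "midparent")
  expect_equal(sort(ds_swap$parent_value), sort(ds$parent_value))

  # offspring identical to midparent value -> slope exactly 1
  ped3 <- validate_pedigree(data.frame(
    id = c("m1", "f1", "m2", "f2", "m3", "f3", "k1", "k2", "k3"),
    sire = c(rep(NA, 6), "m1", "m2", "m3"),
    dam = c(rep(NA, 6), "f1", "f2", "f3"),
    sex = c(rep(c("male", "female"), 3), rep("unknown", 3))))
  lf <- c(1, 2, 2, 4, 3, 6, 1.5, 3, 4.5)
  phen3 <- tibble::tibble(id = ped3$id, log_fid = lf, fid_m = exp(lf),
                          sex = ped3$sex, habitat = "rural", n_measures = 1L)
  ds3 <- build_po_dataset(ped3, phen3, "midparent")
  expect_equal(suppressWarnings(midparent_h2(ds3))$h2, 1)
})

test_that("single-parent estimates double the slope and shrink with mate correlation", {
  st <- simulate_fid_study(sim_config(n_founders = 60, n_generations = 2, seed = 13))
  ds_f <- build_po_dataset(st$pedigree, st$phenotypes, "father")
  ds_m <- build_po_dataset(st$pedigree, st$phenotypes, "mother")

  raw <- ols_slope(ds_f$parent_value, ds_f$offspring_value)
  e0 <- single_parent_h2(ds_f, r = 0)
  expect_identical(e0$h2, 2 * raw$b)
  expect_identical(e0$se, 2 * raw$se_b)
  expect_equal(e0$correction_r, 0)

  # corrected estimate is strictly decreasing in r; limit r -> 1 halves it
  rs <- c(-0.5, 0, 0.3, 0.61, 0.78)
  h2s <- vapply(rs, function(r) single_parent_h2(ds_f, r)$h2, numeric(1))
  expect_true(all(diff(h2s) < 0))
  expect_equal(single_parent_h2(ds_f, 1 - 1e-12)$h2, raw$b, tolerance = 1e-9)
  expect_error(single_parent_h2(ds_f, r = -1), "r")
  expect_error(single_parent_h2(ds_f, r = 1), "r")

  # father and mother datasets share broods but differ in parent values
  shared <- merge(as.data.frame(ds_f), as.data.frame(ds_m), by = c("sire", "dam"))
  expect_gt(nrow(shared), 0)
  expect_false(isTRUE(all.equal(shared$parent_value.x, shared$parent_value.y)))
  expect_equal(shared$offspring_value.x, shared$offspring_value.y)
})

test_that("mate correlation behaves as a Pearson correlation with guards", {
  x <- c(1.2, 2.5, 3.1, 4.0)
  expect_equal(as.numeric(mate_correlation(x, x)), 1)
  expect_equal(as.numeric(mate_correlation(x, -x)), -1)
  expect_error(mate_correlation(x[1:2], x[1:2]), "3 breeding pairs")
  expect_error(mate_correlation(rep(1, 4), x), "variance")

  st <- simulate_fid_study(sim_config(n_founders = 530, n_generations = 2,
                                      mate_r = 0.72, seed = 17))
  mc <- mate_correlations(st$pedigree, st$phenotypes)
  r_all <- mc$r[mc$habitat == "all"]
  expect_gte(mc$n_pairs[mc$habitat == "all"], 264)
  expect_lt(abs(r_all - 0.72), 0.08)
})

test_that("the heritability table stratifies by habitat and records corrections", {
  st <- simulate_fid_study(sim_config(seed = 42))
  tab <- po_heritability(st$pedigree, st$phenotypes)
  expect_setequal(unique(tab$method), c("midparent", "father", "mother"))
  expect_setequal(unique(tab$habitat), c("rural", "urban", "all"))
  expect_true(all(is.na(tab$correction_r[tab$method == "midparent"])))
  expect_true(all(!is.na(tab$correction_r[tab$method != "midparent"])))
  expect_true(all(tab$se > 0))
  # habitat rows use only that stratum's broods
  ds_all <- build_po_dataset(st$pedigree, st$phenotypes, "midparent")
  expect_equal(tab$n[tab$method == "midparent" & tab$habitat == "rural"],
               sum(ds_all$habitat == "rural"))
})
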