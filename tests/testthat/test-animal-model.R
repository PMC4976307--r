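small_fit <- function(seed_sim = 2, seed_chain = 3, n_iter = 3000,
                      burn_in = 500, thin = 5, h2_true = 0.43, ...) {
  st <- simulate_fid_study(sim_config(n_founders = 30, n_generations = 2,
                                      h2_true = h2_true, seed = seed_sim, ...))
  fit <- fit_animal_model(st$phenotypes, st$pedigree,
                          animal_model_spec(n_iter = n_iter, burn_in = burn_in,
                                            thin = thin, seed = seed_chain))
  list(st = st, fit = fit)
}

test_that("sampler settings are validated and the schedule controls storage", {
  expect_error(animal_model_spec(prior_V = 0), "prior_V")
  expect_error(animal_model_spec(n_iter = 100, burn_in = 100), "exceed")
  expect_error(animal_model_spec(thin = 0), "thin")
  expect_error(animal_model_spec(fixed_effects = "year"), "Unknown fixed effect")

  f <- small_fit(n_iter = 1030, burn_in = 100, thin = 7)$fit
  expect_equal(nrow(f$draws), (1030 - 100) %/% 7)
  expect_identical(names(f$draws),
                   c("iteration", "va", "ve", "h2",
                     "(Intercept)", "habitat_urban", "sex_female"))
})

test_that("chains are reproducible for a fixed seed and draws respect positivity", {
  a <- small_fit()$fit
  b <- small_fit()$fit
  expect_identical(a$draws, b$draws)
  c <- small_fit(seed_chain = 4)$fit
  expect_false(identical(a$draws, c$draws))

  expect_true(all(a$draws$va > 0))
  expect_true(all(a$draws$ve > 0))
  expect_true(all(a$draws$h2 > 0 & a$draws$h2 < 1))
})

test_that("phenotyped individuals must be pedigreed with known covariates", {
  st <- simulate_fid_study(sim_config(n_founders = 10, n_generations = 2, seed = 1))
  phen_extra <- dplyr::bind_rows(st$phenotypes,
                                 tibble::tibble(id = "ghost", fid_m = 10,
                                                log_fid = log(10), sex = "female",
                                                habitat = "urban", n_measures = 1L))
  expect_error(fit_animal_model(phen_extra, st$pedigree, desk_schedule()),
               "absent from pedigree")

  ped_bad <- st$pedigree
  ped_bad$sex[5] <- "unknown"
  expect_error(fit_animal_model(st$phenotypes, ped_bad, desk_schedule()),
               "known habitat and sex")

  # unphenotyped pedigree members are allowed: drop some phenotype rows
  fit <- fit_animal_model(st$phenotypes[-(1:4), ], st$pedigree,
                          animal_model_spec(n_iter = 600, burn_in = 100,
                                            thin = 1, seed = 2))
  expect_equal(fit$n_obs, nrow(st$phenotypes) - 4)
  expect_equal(fit$n_ped, nrow(st$pedigree))
})

test_that("without additive variance the habitat effect is detected but h2 stays near zero", {
  st <- simulate_fid_study(sim_config(n_founders = 200, n_generations = 2,
                                      h2_true = 0, seed = 19))
  expect_gte(nrow(st$pedigree), 800)
  fit <- fit_animal_model(st$phenotypes, st$pedigree,
                          animal_model_spec(n_iter = 8000, burn_in = 1000,
                                            thin = 10, seed = 20))
  s <- summarize_posterior(fit)
  expect_lt(s$h2$mean, 0.1)
  hab <- s$fixed[s$fixed$term == "habitat_urban", ]
  expect_true(hab$excludes_zero)
  expect_lt(hab$upper, 0)
})

test_that("HPD intervals match the analytic Beta solution and degenerate cleanly", {
  set.seed(42)
  draws <- rbeta(20000, 20, 30)
  got <- hpd_interval(draws, 0.95)
  want <- oracle_beta_hpd(20, 30, 0.95)
  expect_lt(max(abs(got - want)), 0.02)

  expect_equal(hpd_interval(rep(0.3, 500), 0.95), c(0.3, 0.3))
})

test_that("effective sample size tracks i.i.d. and AR(1) references", {
  set.seed(8)
  iid <- rnorm(5000)
  expect_lt(abs(effective_sample_size(iid) - 5000) / 5000, 0.15)

  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), n = 20000))
  ess_ar <- effective_sample_size(ar)
  want <- 20000 * (1 - phi) / (1 + phi)
  expect_lt(abs(ess_ar - want) / want, 0.25)

  expect_warning(ess0 <- effective_sample_size(rep(1, 200)), "Degenerate")
  expect_equal(ess0, 0)
  expect_error(effective_sample_size(rnorm(50)), "100 draws")
})

test_that("posterior summaries, tidy and glance are coherent", {
  f <- small_fit(n_iter = 6000, burn_in = 1000, thin = 10)
  s <- summarize_posterior(f$fit)
  expect_lt(s$h2$lower, s$h2$upper)
  expect_gt(s$h2$mean, 0); expect_lt(s$h2$mean, 1)
  expect_setequal(s$fixed$term, c("(Intercept)", "habitat_urban", "sex_female"))

  td <- tidy(f$fit)
  expect_setequal(td$term, c(s$fixed$term, "va", "ve", "h2"))
  expect_equal(td$estimate[td$term == "h2"], s$h2$mean)
  gl <- glance(f$fit)
  expect_equal(gl$h2_mean, s$h2$mean)
  expect_equal(gl$n_draws, nrow(f$fit$draws))

  # equal-tailed interval option differs from HPD but brackets the mean
  sq <- summarize_posterior(f$fit, interval = "quantile")
  expect_lt(sq$h2$lower, s$h2$mean)
  expect_gt(sq$h2$upper, s$h2$mean)

  short <- f$fit
  short$draws <- short$draws[1:50, ]
  expect_error(summarize_posterior(short), "100 stored draws")
})

test_that("the posterior is insensitive to the prior scale at nu = 0.02", {
  st <- simulate_fid_study(sim_config(seed = 33))
  means <- vapply(c(0.5, 1, 2), function(V) {
    fit <- fit_animal_model(st$phenotypes, st$pedigree,
                            animal_model_spec(prior_V = V, n_iter = 10000,
                                              burn_in = 1000, thin = 10,
                                              seed = 44))
    mean(fit$draws$h2)
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.05)
})
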