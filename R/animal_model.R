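#' Animal-model sampler settings
#'
#' Settings for the Bayesian animal model of log-FID: which fixed effects to
#' include, the variance-component prior, and the MCMC schedule. The prior
#' on each variance component is a univariate inverse-Wishart, i.e. a scaled
#' inverse-chi-square with scale `prior_V` and degrees of belief `prior_nu`
#' (the default `V = 1`, `nu = 0.02` is effectively uninformative); fixed
#' effects get a flat improper prior.
#'
#' The default schedule (1,000,000 iterations, 10,000 burn-in, thinning
#' 200) suits a final analysis; [desk_schedule()] gives a shorter schedule
#' (50,000 / 5,000 / 50) adequate for simulation studies and calibration.
#'
#' @param fixed_effects Character subset of `c("habitat", "sex")`; an
#'   intercept is always included. Habitat is coded urban-vs-rural
#'   (indicator of urban) and sex female-vs-male (indicator of female).
#' @param prior_V Prior scale for both variance components (> 0).
#' @param prior_nu Prior degrees of belief (> 0).
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before storage (< `n_iter`).
#' @param thin Store every `thin`-th post-burn-in iteration.
#' @param seed Integer RNG seed; chains are reproducible given the seed.
#' @return A list of class `animal_model_spec`.
#' @export
animal_model_spec <- function(fixed_effects = c("habitat", "sex"),
                              prior_V = 1, prior_nu = 0.02,
                              n_iter = 1e6, burn_in = 1e4, thin = 200,
                              seed = 1L) {
  if (prior_V <= 0 || prior_nu <= 0) abort("`prior_V` and `prior_nu` must be > 0.")
  if (n_iter <= burn_in) abort("`n_iter` must exceed `burn_in`.")
  if (thin < 1) abort("`thin` must be >= 1.")
  bad <- setdiff(fixed_effects, c("habitat", "sex"))
  if (length(bad)) abort(paste0("Unknown fixed effect(s): ", paste(bad, collapse = ", "), "."))
  structure(list(fixed_effects = fixed_effects, prior_V = prior_V,
                 prior_nu = prior_nu, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "animal_model_spec")
}

#' @rdname animal_model_spec
#' @param ... Overrides passed to [animal_model_spec()].
#' @export
desk_schedule <- function(...) {
  animal_model_spec(n_iter = 5e4, burn_in = 5e3, thin = 50, ...)
}

#' Fit the Bayesian animal model for log-FID by Gibbs sampling
#'
#' Mixed model `y = X beta + Z a + e` with `a ~ N(0, A sigma2_A)` over the
#' pedigree relationship matrix A and `e ~ N(0, I sigma2_R)`. The Gibbs
#' sweep draws, in turn: the fixed effects from their Gaussian full
#' conditional; all breeding values jointly from the mixed-model-equation
#' Gaussian conditional, via a sparse Cholesky factorisation of
#' `Z'Z + (sigma2_R / sigma2_A) A^-1` whose symbolic analysis is reused
#' across iterations; and each variance component from its scaled
#' inverse-chi-square conditional (df `nu + q`, scale
#' `(a' A^-1 a + nu V) / (nu + q)` for the additive component, analogously
#' from the residuals). Unphenotyped pedigree members simply receive
#' breeding values; phenotyped individuals must be in the pedigree.
#'
#' @param phen Phenotype tibble (`id`, `log_fid`; one row per individual).
#' @param ped A validated pedigree with known habitat and sex for every
#'   phenotyped individual.
#' @param spec An [animal_model_spec()].
#' @return An object of class `animal_model`: list with `draws` (tibble of
#'   stored samples: `iteration`, `va`, `ve`, `h2` and one column per fixed
#'   effect), `spec`, `terms`, `n_obs`, `n_ped`.
#' @export
fit_animal_model <- function(phen, ped, spec = animal_model_spec()) {
  assert_pedigree(ped)
  stopifnot(inherits(spec, "animal_model_spec"))
  missing_ids <- setdiff(phen$id, ped$id)
  if (length(missing_ids)) {
    abort(paste0("Phenotyped individual(s) absent from pedigree: ",
                 paste(utils::head(missing_ids, 5), collapse = ", "), "."))
  }
  idx <- match(phen$id, ped$id)
  if (anyDuplicated(idx)) abort("Expected one phenotype row per individual.")
  if (("habitat" %in% spec$fixed_effects && any(ped$habitat[idx] == "unknown")) ||
      ("sex" %in% spec$fixed_effects && any(ped$sex[idx] == "unknown"))) {
    abort("Phenotyped individuals must have known habitat and sex.")
  }

  y <- phen$log_fid
  n <- length(y)
  q <- nrow(ped)
  terms <- "(Intercept)"
  X <- matrix(1, n, 1)
  if ("habitat" %in% spec$fixed_effects) {
    X <- cbind(X, as.numeric(ped$habitat[idx] == "urban"))
    terms <- c(terms, "habitat_urban")
  }
  if ("sex" %in% spec$fixed_effects) {
    X <- cbind(X, as.numeric(ped$sex[idx] == "female"))
    terms <- c(terms, "sex_female")
  }
  colnames(X) <- terms
  p <- ncol(X)

  Ainv <- a_inverse(ped)
  Ct <- as(Ainv, "CsparseMatrix")              # dsCMatrix template, upper
  ainv_x <- Ct@x
  col_of <- rep.int(seq_len(q), diff(Ct@p))
  dpos <- which(Ct@i == col_of - 1L)           # diagonal slots in @x
  znn <- tabulate(idx, nbins = q)              # Z'Z diagonal (0/1 here)

  Rx <- chol(crossprod(X))
  Xt <- t(X)

  set.seed(spec$seed)
  vy <- var(y)
  va <- vy / 2
  ve <- vy / 2
  a <- numeric(q)
  beta <- rep(0, p)
  nu <- spec$prior_nu
  nuV <- spec$prior_nu * spec$prior_V

  lam0 <- ve / va
  Ct@x <- ainv_x * lam0
  Ct@x[dpos] <- Ct@x[dpos] + znn
  ch <- tryCatch(
    Matrix::Cholesky(Ct, LDL = FALSE, perm = TRUE),
    error = function(e) abort(paste0(
      "Mixed-model system matrix is not positive definite: ", conditionMessage(e)))
  )

  n_store <- (spec$n_iter - spec$burn_in) %/% spec$thin
  if (n_store < 1) abort("Schedule stores no draws; increase `n_iter`.")
  S_va <- numeric(n_store); S_ve <- numeric(n_store)
  S_beta <- matrix(NA_real_, n_store, p, dimnames = list(NULL, terms))
  S_iter <- integer(n_store)
  k <- 0L

  for (it in seq_len(spec$n_iter)) {
    # fixed effects | a, ve
    r1 <- y - a[idx]
    bhat <- backsolve(Rx, forwardsolve(t(Rx), Xt %*% r1))
    beta <- bhat + sqrt(ve) * backsolve(Rx, rnorm(p))
    xb <- drop(X %*% beta)

    # breeding values | beta, va, ve (joint draw)
    r2 <- y - xb
    ztr <- numeric(q)
    ztr[idx] <- r2
    Ct@x <- ainv_x * (ve / va)
    Ct@x[dpos] <- Ct@x[dpos] + znn
    ch <- Matrix::update(ch, Ct)
    mu_a <- Matrix::solve(ch, ztr, system = "A")
    w <- Matrix::solve(ch, rnorm(q), system = "Lt")
    a <- as.numeric(mu_a) + sqrt(ve) * as.numeric(Matrix::solve(ch, w, system = "Pt"))

    # variance components | a, residuals
    qa <- as.numeric(Matrix::crossprod(a, Ainv %*% a))
    va <- (qa + nuV) / rchisq(1, nu + q)
    e <- r2 - a[idx]
    ve <- (sum(e * e) + nuV) / rchisq(1, nu + n)

    if (it > spec$burn_in && (it - spec$burn_in) %% spec$thin == 0L) {
      k <- k + 1L
      S_va[k] <- va; S_ve[k] <- ve; S_beta[k, ] <- beta; S_iter[k] <- it
    }
  }

  draws <- tibble(iteration = S_iter, va = S_va, ve = S_ve,
                  h2 = S_va / (S_va + S_ve))
  for (j in seq_len(p)) draws[[terms[j]]] <- S_beta[, j]
  structure(list(draws = draws, spec = spec, terms = terms,
                 n_obs = n, n_ped = q),
            class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  s <- summarize_posterior(x)
  cat(sprintf(
    "<animal_model> %d phenotypes, %d pedigree members, %d stored draws\n",
    x$n_obs, x$n_ped, nrow(x$draws)))
  cat(sprintf("  h2: mean %.3f, mode %.3f, 95%% HPD [%.3f, %.3f]\n",
              s$h2$mean, s$h2$mode, s$h2$lower, s$h2$upper))
  invisible(x)
}

#' Highest-posterior-density interval of a sample
#'
#' Shortest interval containing a fraction `prob` of the draws (empirical
#' HPD on the sorted sample).
#'
#' @param x Numeric draws.
#' @param prob Coverage probability.
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  n <- length(x)
  if (n < 2) return(c(x[1], x[1]))
  xs <- sort(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(xs[1], xs[n]))
  starts <- seq_len(n - m + 1L)
  widths <- xs[starts + m - 1L] - xs[starts]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}

posterior_mode <- function(x) {
  if (var(x) == 0) return(x[1])
  d <- density(x)
  d$x[which.max(d$y)]
}

#' Effective sample size of an MCMC chain
#'
#' Geyer's initial-positive-sequence estimator: autocorrelations are summed
#' over consecutive lag pairs until a pair sum turns non-positive, and
#' `ess = n / (2 S - 1)` with S the truncated pair sum. For a constant
#' (degenerate) chain a warning is issued and 0 returned.
#'
#' @param x Numeric chain (>= 100 draws).
#' @return Effective sample size (capped at the number of draws).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 100) abort("At least 100 draws are required.")
  if (var(x) == 0) {
    warn("Degenerate (constant) chain; effective sample size undefined.")
    return(0)
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)
  n_pairs <- (length(rho)) %/% 2
  s <- 0
  for (m in seq_len(n_pairs)) {
    g <- rho[2 * m - 1] + rho[2 * m]
    if (g <= 0) break
    s <- s + g
  }
  tau <- max(2 * s - 1, 1)
  min(n / tau, n)
}

#' Summarise animal-model posterior draws
#'
#' Per-draw heritability `h2 = va / (va + ve)` is summarised by its
#' posterior mean, kernel-density mode and highest-posterior-density
#' interval; each fixed effect by its posterior mean, interval and a flag
#' for whether the interval excludes zero (the usual significance
#' criterion for Bayesian fixed effects); variance components likewise.
#'
#' @param fit An `animal_model` object (>= 100 stored draws).
#' @param ci_level Interval coverage (default 0.95).
#' @param interval `"hpd"` (default) or `"quantile"` (equal-tailed).
#' @return A list of class `animal_model_summary`: `h2` (mean, mode, lower,
#'   upper, ess), `fixed` (tibble per term), `variances` (tibble for va,
#'   ve), `n_draws`, `ci_level`.
#' @export
summarize_posterior <- function(fit, ci_level = 0.95,
                                interval = c("hpd", "quantile")) {
  stopifnot(inherits(fit, "animal_model"))
  interval <- match.arg(interval)
  d <- fit$draws
  if (nrow(d) < 100) abort("At least 100 stored draws are required to summarise.")
  ci_fun <- function(x) {
    if (interval == "hpd") hpd_interval(x, ci_level)
    else unname(quantile(x, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)))
  }
  h2_ci <- ci_fun(d$h2)
  fixed <- purrr::map_dfr(fit$terms, function(tm) {
    ci <- ci_fun(d[[tm]])
    tibble(term = tm, mean = mean(d[[tm]]), lower = ci[1], upper = ci[2],
           excludes_zero = ci[1] > 0 || ci[2] < 0,
           ess = effective_sample_size(d[[tm]]))
  })
  variances <- purrr::map_dfr(c("va", "ve"), function(v) {
    ci <- ci_fun(d[[v]])
    tibble(component = v, mean = mean(d[[v]]), mode = posterior_mode(d[[v]]),
           lower = ci[1], upper = ci[2], ess = effective_sample_size(d[[v]]))
  })
  structure(list(
    h2 = list(mean = mean(d$h2), mode = posterior_mode(d$h2),
              lower = h2_ci[1], upper = h2_ci[2],
              ess = effective_sample_size(d$h2)),
    fixed = fixed, variances = variances,
    n_draws = nrow(d), ci_level = ci_level
  ), class = "animal_model_summary")
}

#' @export
summary.animal_model <- function(object, ...) summarize_posterior(object, ...)

#' @export
print.animal_model_summary <- function(x, ...) {
  cat(sprintf("Posterior h2: mean %.3f, mode %.3f, %d%% interval [%.3f, %.3f] (ESS %.0f)\n",
              x$h2$mean, x$h2$mode, round(100 * x$ci_level),
              x$h2$lower, x$h2$upper, x$h2$ess))
  cat("\nFixed effects:\n"); print(x$fixed)
  cat("\nVariance components:\n"); print(x$variances)
  invisible(x)
}

#' Tidy the posterior of a fitted animal model
#'
#' @param x An `animal_model`.
#' @param ci_level,interval Passed to [summarize_posterior()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (fixed effects, `va`, `ve`,
#'   `h2`): `term`, `estimate` (posterior mean), `mode`, `conf.low`,
#'   `conf.high`, `ess`.
#' @export
tidy.animal_model <- function(x, ci_level = 0.95, interval = "hpd", ...) {
  s <- summarize_posterior(x, ci_level, interval)
  bind_rows(
    s$fixed |>
      mutate(mode = purrr::map_dbl(.data$term, ~ posterior_mode(x$draws[[.x]]))) |>
      select(term = "term", estimate = "mean", "mode",
             conf.low = "lower", conf.high = "upper", "ess"),
    s$variances |>
      select(term = "component", estimate = "mean", "mode",
             conf.low = "lower", conf.high = "upper", "ess"),
    tibble(term = "h2", estimate = s$h2$mean, mode = s$h2$mode,
           conf.low = s$h2$lower, conf.high = s$h2$upper, ess = s$h2$ess)
  )
}

#' One-row summary of a fitted animal model
#'
#' @inheritParams tidy.animal_model
#' @return A one-row tibble: `h2_mean`, `h2_mode`, `h2_conf_low`,
#'   `h2_conf_high`, `ess_h2`, `n_draws`, `n_obs`, `n_pedigree`.
#' @export
glance.animal_model <- function(x, ...) {
  s <- summarize_posterior(x)
  tibble(h2_mean = s$h2$mean, h2_mode = s$h2$mode,
         h2_conf_low = s$h2$lower, h2_conf_high = s$h2$upper,
         ess_h2 = s$h2$ess, n_draws = s$n_draws,
         n_obs = x$n_obs, n_pedigree = x$n_ped)
}
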