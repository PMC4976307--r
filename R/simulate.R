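#' Configuration for the synthetic FID study generator
#'
#' Bundles the parameters of the simulated study design: a multi-generation
#' pedigree split across an urban and a rural habitat, log-FID phenotypes
#' with additive genetic variance, habitat and sex fixed effects, phenotypic
#' assortative mating, and natal-habitat philopatry.
#'
#' Defaults emulate the design the package targets: roughly 1,200
#' individuals over 3 generations, heritability 0.43 on a unit total
#' phenotypic variance of log-FID, urban birds shyer by 0.42 on the log
#' scale (i.e. shorter flight initiation distances), females bolder by 0.06,
#' and a phenotypic correlation of 0.78 between mates.
#'
#' @param n_founders Founders per habitat in generation 0.
#' @param n_generations Number of generation layers (>= 2).
#' @param mean_brood Expected brood size per breeding pair (Poisson mean,
#'   truncated at `max_brood`).
#' @param max_brood Upper truncation for brood size.
#' @param h2_true Target narrow-sense heritability of log-FID in the founder
#'   (base) population, in [0, 1].
#' @param VP_total Total phenotypic variance of log-FID (> 0).
#' @param beta_habitat Fixed effect of urban habitat on log-FID (default
#'   -0.42: urban birds flee at shorter distances).
#' @param beta_sex Fixed effect of female sex on log-FID (default +0.06).
#' @param mu Intercept: expected log-FID of a rural male with average
#'   breeding value.
#' @param mate_r Target phenotypic correlation between mates, |r| < 1.
#' @param philopatry Probability that an offspring settles (and later breeds)
#'   in its natal habitat.
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 140,
                       n_generations = 3,
                       mean_brood = 2.8,
                       max_brood = 8,
                       h2_true = 0.43,
                       VP_total = 1,
                       beta_habitat = -0.42,
                       beta_sex = 0.06,
                       mu = 3.4,
                       mate_r = 0.78,
                       philopatry = 1,
                       seed = 1L) {
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              mean_brood = mean_brood, max_brood = max_brood,
              h2_true = h2_true, VP_total = VP_total,
              beta_habitat = beta_habitat, beta_sex = beta_sex, mu = mu,
              mate_r = mate_r, philopatry = philopatry, seed = seed)
  if (cfg$h2_true < 0 || cfg$h2_true > 1) abort("`h2_true` must be in [0, 1].")
  if (cfg$VP_total <= 0) abort("`VP_total` must be > 0.")
  if (abs(cfg$mate_r) >= 1) abort("`mate_r` must satisfy |r| < 1.")
  if (cfg$n_generations < 2) abort("`n_generations` must be >= 2.")
  if (cfg$n_founders < 2) abort("`n_founders` must be >= 2 per habitat.")
  if (cfg$philopatry < 0 || cfg$philopatry > 1) abort("`philopatry` must be in [0, 1].")
  structure(cfg, class = "sim_config")
}

#' Pair breeding candidates with phenotypic assortative mating
#'
#' Monogamous rank-matching: each male is assigned a latent value correlated
#' `mate_r` with his phenotype, and phenotype-sorted females are paired with
#' latent-sorted males. For Gaussian phenotypes this realises a Pearson
#' correlation between mate phenotypes close to `mate_r`; `mate_r = 0` is
#' random pairing, and as `mate_r` approaches 1 the pairing tends to exact
#' rank-sorted matching. When the sexes differ in number, a random subset of
#' the more numerous sex of the size of the other enters the pairing.
#'
#' @param female_phen,male_phen Named numeric vectors of candidate
#'   phenotypes (names are individual ids).
#' @param mate_r Target phenotypic correlation between mates, |r| < 1.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `female`, `male` (ids) and the paired
#'   phenotypes `female_phen`, `male_phen`; each individual appears in at
#'   most one pair.
#' @export
assign_mates_assortative <- function(female_phen, male_phen, mate_r,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(mate_r) >= 1) abort("`mate_r` must satisfy |r| < 1.")
  if (length(female_phen) < 1 || length(male_phen) < 1) {
    abort("Need at least one candidate of each sex.")
  }
  np <- min(length(female_phen), length(male_phen))
  f <- female_phen[sort(sample.int(length(female_phen), np))]
  m <- male_phen[sort(sample.int(length(male_phen), np))]
  mz <- if (np > 1 && sd(m) > 0) as.numeric(scale(m)) else rep(0, np)
  latent <- mate_r * mz + sqrt(1 - mate_r^2) * rnorm(np)
  of <- order(f)
  ol <- order(latent)
  tibble(female = names(f)[of], male = names(m)[ol],
         female_phen = unname(f[of]), male_phen = unname(m[ol]))
}

#' Simulate breeding values over an existing pedigree
#'
#' Additive-infinitesimal transmission: founders are drawn from
#' `Normal(0, VA)`; a non-founder receives the mean of its known parents'
#' values plus a Mendelian sampling deviation with variance
#' `0.5 VA (1 - 0.5 (F_sire + F_dam))` (both parents known),
#' `VA (0.75 - 0.25 F_p)` (one known parent p), or `VA` (founder), with F
#' the parental inbreeding coefficients.
#'
#' @param ped A validated pedigree.
#' @param VA Additive genetic variance (>= 0).
#' @param seed Optional seed.
#' @return A tibble `id`, `bv` in pedigree order with attribute `"VA"`.
#' @export
simulate_breeding_values <- function(ped, VA, seed = NULL) {
  assert_pedigree(ped)
  if (VA < 0) abort("`VA` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  Fv <- inbreeding_coefficients(ped)
  a <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) {
      a[i] <- rnorm(1, 0, sqrt(VA))
    } else if (!is.na(s) && !is.na(d)) {
      v <- 0.5 * VA * (1 - 0.5 * (Fv[[s]] + Fv[[d]]))
      a[i] <- 0.5 * (a[s] + a[d]) + rnorm(1, 0, sqrt(v))
    } else {
      p <- if (is.na(s)) d else s
      v <- VA * (0.75 - 0.25 * Fv[[p]])
      a[i] <- 0.5 * a[p] + rnorm(1, 0, sqrt(v))
    }
  }
  structure(tibble(id = ids, bv = a), VA = VA)
}

#' Simulate log-FID phenotypes over a pedigree with known breeding values
#'
#' `log_fid = mu + beta_habitat [urban] + beta_sex [female] + bv + e`,
#' `e ~ Normal(0, VE)` with `VE = VP_total (1 - h2_true)`; FID in meters is
#' `exp(log_fid)`.
#'
#' @param ped A validated pedigree with known habitat and sex for every
#'   individual.
#' @param bv Breeding values as returned by [simulate_breeding_values()].
#' @param cfg A [sim_config()] supplying `mu`, the fixed effects and `VE`.
#' @param seed Optional seed.
#' @return A phenotype tibble: `id`, `fid_m`, `log_fid`, `sex`, `habitat`,
#'   `n_measures` (all 1).
#' @export
simulate_phenotypes <- function(ped, bv, cfg, seed = NULL) {
  assert_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  if (!all(ped$id %in% bv$id)) abort("`bv` must cover every pedigree id.")
  if (any(ped$habitat == "unknown") || any(ped$sex == "unknown")) {
    abort("Phenotype simulation requires known habitat and sex for every individual.")
  }
  VE <- cfg$VP_total * (1 - cfg$h2_true)
  a <- bv$bv[match(ped$id, bv$id)]
  y <- cfg$mu +
    cfg$beta_habitat * (ped$habitat == "urban") +
    cfg$beta_sex * (ped$sex == "female") +
    a + rnorm(nrow(ped), 0, sqrt(VE))
  tibble(id = ped$id, fid_m = exp(y), log_fid = y,
         sex = ped$sex, habitat = ped$habitat, n_measures = 1L)
}

#' Simulate a complete synthetic FID study
#'
#' Generates pedigree, breeding values and phenotypes jointly, generation by
#' generation, because mate choice is phenotypic: founders are split across
#' the two habitats, each later generation is formed by assortatively
#' pairing the previous generation's residents within habitat
#' ([assign_mates_assortative()]), brood sizes are truncated-Poisson, sexes
#' are assigned at random, and offspring settle in their natal habitat with
#' probability `philopatry`. Breeding values follow the additive model of
#' [simulate_breeding_values()], with Mendelian sampling variance adjusted
#' for parental inbreeding tracked through the growing relationship matrix.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `fid_study`: `pedigree` (validated), `phenotypes`
#'   (one row per individual), `breeding_values`, and `truth` (the
#'   generating parameter values: VA, VE, h2_true, beta_habitat, beta_sex,
#'   mu, mate_r, seed).
#' @export
simulate_fid_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  VA <- cfg$VP_total * cfg$h2_true
  VE <- cfg$VP_total * (1 - cfg$h2_true)
  habitats <- c("urban", "rural")

  # Parental inbreeding can first be non-zero in generation 2 (offspring of
  # related generation-1 parents), so Mendelian sampling variance needs
  # tracked relatedness only for pedigrees deeper than 3 layers; founders
  # are unrelated and non-inbred by convention.
  track_F <- cfg$n_generations > 3L

  cap <- 2048L
  id <- character(cap); sire <- character(cap); dam <- character(cap)
  sex <- character(cap); habitat <- character(cap); generation <- integer(cap)
  bv <- numeric(cap); y <- numeric(cap)
  A <- if (track_F) matrix(0, cap, cap) else NULL
  n <- 0L

  grow <- function() {
    cap2 <- 2L * cap
    id <<- c(id, character(cap)); sire <<- c(sire, character(cap))
    dam <<- c(dam, character(cap)); sex <<- c(sex, character(cap))
    habitat <<- c(habitat, character(cap)); generation <<- c(generation, integer(cap))
    bv <<- c(bv, numeric(cap)); y <<- c(y, numeric(cap))
    if (track_F) {
      A2 <- matrix(0, cap2, cap2); A2[1:cap, 1:cap] <- A; A <<- A2
    }
    cap <<- cap2
  }

  # s, d are indices into the arrays (NA for founders)
  add_individual <- function(iid, s, d, sx, hb, gen, a_val) {
    if (n + 1L > cap) grow()
    i <- n + 1L
    id[i] <<- iid
    sire[i] <<- if (is.na(s)) NA_character_ else id[s]
    dam[i] <<- if (is.na(d)) NA_character_ else id[d]
    sex[i] <<- sx
    habitat[i] <<- hb; generation[i] <<- gen; bv[i] <<- a_val
    y[i] <<- cfg$mu + cfg$beta_habitat * (hb == "urban") +
      cfg$beta_sex * (sx == "female") + a_val + rnorm(1, 0, sqrt(VE))
    if (track_F) {
      if (is.na(s)) {
        A[i, i] <<- 1
      } else {
        js <- seq_len(i - 1L)
        aij <- 0.5 * (A[js, s] + A[js, d])
        A[js, i] <<- aij; A[i, js] <<- aij
        A[i, i] <<- 1 + 0.5 * A[s, d]
      }
    }
    n <<- i
    i
  }
  inbreeding_of <- function(i) if (track_F) A[i, i] - 1 else 0

  # generation 0: founders
  for (hb in habitats) {
    sexes <- sample(rep(c("female", "male"), length.out = cfg$n_founders))
    for (k in seq_len(cfg$n_founders)) {
      add_individual(sprintf("%s0_%03d", substr(hb, 1, 1), k),
                     NA_integer_, NA_integer_, sexes[k], hb, 0L,
                     rnorm(1, 0, sqrt(VA)))
    }
  }

  for (gen in seq_len(cfg$n_generations - 1L)) {
    parents <- which(generation[1:n] == gen - 1L)
    pairs_total <- 0L
    child_k <- 0L
    for (hb in habitats) {
      cand <- parents[habitat[parents] == hb]
      fem <- cand[sex[cand] == "female"]
      mal <- cand[sex[cand] == "male"]
      if (!length(fem) || !length(mal)) next
      pairs <- assign_mates_assortative(setNames(y[fem], id[fem]),
                                        setNames(y[mal], id[mal]),
                                        cfg$mate_r)
      pairs_total <- pairs_total + nrow(pairs)
      fem_idx <- match(pairs$female, id[1:n])
      mal_idx <- match(pairs$male, id[1:n])
      for (p in seq_len(nrow(pairs))) {
        dmi <- fem_idx[p]
        sri <- mal_idx[p]
        brood <- min(rpois(1, cfg$mean_brood), cfg$max_brood)
        if (brood < 1) next
        mend_sd <- sqrt(0.5 * VA * (1 - 0.5 * (inbreeding_of(sri) + inbreeding_of(dmi))))
        for (b in seq_len(brood)) {
          child_k <- child_k + 1L
          hb_child <- if (runif(1) <= cfg$philopatry) hb else setdiff(habitats, hb)
          add_individual(sprintf("%s%d_%04d", substr(hb, 1, 1), gen, child_k),
                         sri, dmi,
                         sample(c("female", "male"), 1L), hb_child, gen,
                         0.5 * (bv[sri] + bv[dmi]) + rnorm(1, 0, mend_sd))
        }
      }
    }
    if (pairs_total == 0L) {
      abort(sprintf("Population extinct: no breeding pairs could be formed in generation %d.", gen))
    }
  }

  keep <- seq_len(n)
  ped <- validate_pedigree(tibble(
    id = id[keep], sire = ifelse(sire[keep] == "" | is.na(sire[keep]), NA, sire[keep]),
    dam = ifelse(dam[keep] == "" | is.na(dam[keep]), NA, dam[keep]),
    sex = sex[keep], habitat = habitat[keep]
  ))
  ord <- match(ped$id, id[keep])
  structure(list(
    pedigree = ped,
    phenotypes = tibble(id = ped$id, fid_m = exp(y[keep][ord]),
                        log_fid = y[keep][ord], sex = ped$sex,
                        habitat = ped$habitat, n_measures = 1L),
    breeding_values = structure(tibble(id = ped$id, bv = bv[keep][ord]), VA = VA),
    truth = list(VA = VA, VE = VE, h2_true = cfg$h2_true,
                 beta_habitat = cfg$beta_habitat, beta_sex = cfg$beta_sex,
                 mu = cfg$mu, mate_r = cfg$mate_r, seed = cfg$seed)
  ), class = "fid_study")
}

#' @export
print.fid_study <- function(x, ...) {
  cat(sprintf("<fid_study> %d individuals (%d urban / %d rural), %d generations, true h2 = %.2f\n",
              nrow(x$pedigree), sum(x$pedigree$habitat == "urban"),
              sum(x$pedigree$habitat == "rural"),
              max(x$pedigree$generation) + 1L, x$truth$h2_true))
  invisible(x)
}

#' Simulate only the pedigree of a synthetic study
#'
#' Convenience wrapper around [simulate_fid_study()] returning just the
#' pedigree (pairing is phenotypic, so phenotypes are generated internally
#' even when only the pedigree is wanted).
#'
#' @inheritParams simulate_fid_study
#' @return A validated pedigree.
#' @export
simulate_pedigree <- function(cfg = sim_config()) {
  simulate_fid_study(cfg)$pedigree
}

#' Expand a phenotype table into repeated raw measures
#'
#' Emulates field data in which some individuals were approached more than
#' once: each individual's latent log-FID is re-observed `n_measures` times
#' with within-individual noise chosen so that the repeatability of the raw
#' measures is `repeatability`. Useful for exercising the
#' mean-before-log ingestion path of [read_phenotypes()].
#'
#' @param phen A phenotype tibble (one row per individual).
#' @param n_measures Measures per individual (recycled).
#' @param repeatability Intra-class correlation of raw measures, in (0, 1].
#' @param seed Optional seed.
#' @return A long tibble `id`, `fid_m` with one row per measure.
#' @export
expand_repeated_measures <- function(phen, n_measures = 2, repeatability = 0.9,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (repeatability <= 0 || repeatability > 1) {
    abort("`repeatability` must be in (0, 1].")
  }
  nm <- rep_len(n_measures, nrow(phen))
  v_between <- var(phen$log_fid)
  v_within <- v_between * (1 / repeatability - 1)
  purrr::map2_dfr(seq_len(nrow(phen)), nm, function(i, k) {
    tibble(id = phen$id[i],
           fid_m = exp(phen$log_fid[i] + rnorm(k, 0, sqrt(v_within))))
  })
}
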