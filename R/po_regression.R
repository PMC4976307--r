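#' Build a parent-offspring regression dataset
#'
#' Groups measured offspring into full-sib broods (shared sire and dam) and
#' pairs each brood's mean log-FID with a parental value: the midparent mean
#' (`mode = "midparent"`, both parents must be measured), the sire's value
#' (`"father"`) or the dam's value (`"mother"`). Averaging full sibs avoids
#' pseudo-replication; broods are unweighted downstream regardless of size.
#' A brood's habitat is the natal habitat of its (measured) offspring
#' (majority vote, first level on ties).
#'
#' @param ped A validated pedigree.
#' @param phen A phenotype tibble with columns `id` and `log_fid` (log
#'   meters), as produced by [read_phenotypes()] or [simulate_phenotypes()].
#' @param mode One of `"midparent"`, `"father"`, `"mother"`.
#' @return A tibble of class `po_dataset`, one row per brood: `sire`, `dam`,
#'   `parent_value`, `offspring_value`, `brood_size`, `habitat`, `mode`.
#' @export
build_po_dataset <- function(ped, phen, mode = c("midparent", "father", "mother")) {
  assert_pedigree(ped)
  mode <- match.arg(mode)
  stopifnot(all(c("id", "log_fid") %in% names(phen)))
  lf <- setNames(phen$log_fid, phen$id)

  off <- ped[!(is.na(ped$sire) & is.na(ped$dam)), ]
  off <- off[off$id %in% phen$id, ]
  off$off_value <- unname(lf[off$id])
  need_sire <- mode %in% c("midparent", "father")
  need_dam <- mode %in% c("midparent", "mother")
  if (need_sire) off <- off[!is.na(off$sire) & off$sire %in% names(lf), ]
  if (need_dam) off <- off[!is.na(off$dam) & off$dam %in% names(lf), ]
  if (nrow(off) == 0) abort("No broods with the required measured parent(s).")

  ds <- off |>
    mutate(sire_lf = unname(lf[.data$sire]), dam_lf = unname(lf[.data$dam])) |>
    group_by(.data$sire, .data$dam) |>
    summarise(
      parent_value = switch(mode,
        midparent = (first(.data$sire_lf) + first(.data$dam_lf)) / 2,
        father = first(.data$sire_lf),
        mother = first(.data$dam_lf)
      ),
      offspring_value = mean(.data$off_value),
      brood_size = dplyr::n(),
      habitat = names(sort(table(.data$habitat), decreasing = TRUE))[1],
      .groups = "drop"
    ) |>
    mutate(mode = mode)
  class(ds) <- c("po_dataset", class(ds))
  ds
}

#' Ordinary least-squares slope with standard error and t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 3; `x` must vary).
#' @return A one-row tibble: `b` (slope), `se_b`, `p` (two-sided t-test of
#'   slope = 0), `n`.
#' @export
ols_slope <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("At least 3 points are required.")
  if (var(x) == 0) abort("`x` has zero variance; the slope is undefined.")
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  tibble(b = cf["x", "Estimate"], se_b = cf["x", "Std. Error"],
         p = cf["x", "Pr(>|t|)"], n = length(x))
}

#' Heritability from the midparent-midoffspring regression
#'
#' The slope of brood-mean offspring log-FID on the midparent value
#' estimates h2 directly; phenotypic assortative mating does not bias this
#' regression, so no correction is applied.
#'
#' @param ds A `po_dataset` built with `mode = "midparent"`.
#' @param habitat Label recorded in the result (the stratum the dataset
#'   represents), default `"all"`.
#' @return A one-row tibble of class `h2_estimate`: `method`, `habitat`,
#'   `h2`, `se`, `n`, `p`, `correction_r` (NA).
#' @export
midparent_h2 <- function(ds, habitat = "all") {
  stopifnot(inherits(ds, "po_dataset"))
  if (!all(ds$mode == "midparent")) abort("`ds` must be a midparent dataset.")
  est <- ols_slope(ds$parent_value, ds$offspring_value)
  new_h2_estimate(tibble(method = "midparent", habitat = habitat,
                         h2 = est$b, se = est$se_b, n = est$n, p = est$p,
                         correction_r = NA_real_))
}

#' Heritability from a single-parent regression, corrected for assortative mating
#'
#' Twice the regression slope of brood-mean offspring on one parent
#' estimates h2 under random mating; phenotypic assortative mating with
#' mate correlation r inflates the single-parent regression by (1 + r), so
#' the estimator is `h2 = 2 b / (1 + r)`. The standard error scales by the
#' same linear factor, `se = 2 se_b / (1 + r)`; with `r = 0` this reduces
#' to the classical doubled slope.
#'
#' @param ds A `po_dataset` built with `mode = "father"` or `"mother"`.
#' @param r Phenotypic correlation between mates (|r| < 1), e.g. from
#'   [mate_correlation()].
#' @inheritParams midparent_h2
#' @return A one-row `h2_estimate` tibble with `correction_r = r`.
#' @export
single_parent_h2 <- function(ds, r = 0, habitat = "all") {
  stopifnot(inherits(ds, "po_dataset"))
  mode <- ds$mode[1]
  if (!mode %in% c("father", "mother")) {
    abort("`ds` must be a father- or mother-offspring dataset.")
  }
  if (r <= -1 || r >= 1) abort("`r` must satisfy |r| < 1.")
  est <- ols_slope(ds$parent_value, ds$offspring_value)
  fac <- 2 / (1 + r)
  new_h2_estimate(tibble(method = mode, habitat = habitat,
                         h2 = fac * est$b, se = fac * est$se_b,
                         n = est$n, p = est$p, correction_r = r))
}

new_h2_estimate <- function(x) {
  class(x) <- c("h2_estimate", class(tibble()))
  x
}

#' Phenotypic correlation between mates
#'
#' Pearson correlation of the log-FID values of breeding-pair members.
#'
#' @param female,male Numeric vectors of paired phenotypes (>= 3 pairs),
#'   or a two-column data frame passed as `female`.
#' @return The correlation coefficient (numeric scalar) with attribute
#'   `"n_pairs"`.
#' @export
mate_correlation <- function(female, male = NULL) {
  if (is.data.frame(female)) {
    stopifnot(ncol(female) >= 2)
    male <- female[[2]]
    female <- female[[1]]
  }
  if (length(female) != length(male)) abort("Unequal numbers of mates.")
  if (length(female) < 3) abort("At least 3 breeding pairs are required.")
  if (var(female) == 0 || var(male) == 0) {
    abort("Zero variance in one pair member; correlation undefined.")
  }
  structure(cor(female, male), n_pairs = length(female))
}

#' Breeding pairs observed in a pedigree, with phenotypes
#'
#' Every distinct (sire, dam) combination with both parents known and
#' measured, together with the parents' log-FID and the habitat in which the
#' pair bred (natal habitat of the brood, majority vote).
#'
#' @inheritParams build_po_dataset
#' @return A tibble: `dam`, `sire`, `female_lf`, `male_lf`, `habitat`.
#' @export
mate_pairs <- function(ped, phen) {
  assert_pedigree(ped)
  lf <- setNames(phen$log_fid, phen$id)
  off <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  off <- off[off$sire %in% names(lf) & off$dam %in% names(lf), ]
  if (nrow(off) == 0) abort("No breeding pairs with both members measured.")
  off |>
    group_by(.data$sire, .data$dam) |>
    summarise(habitat = names(sort(table(.data$habitat), decreasing = TRUE))[1],
              .groups = "drop") |>
    mutate(female_lf = unname(lf[.data$dam]), male_lf = unname(lf[.data$sire])) |>
    select("dam", "sire", "female_lf", "male_lf", "habitat")
}

#' Mate correlations by habitat stratum
#'
#' @inheritParams build_po_dataset
#' @return A tibble `habitat` (`"urban"`, `"rural"`, `"all"`), `r`,
#'   `n_pairs`; strata with fewer than 3 pairs are dropped.
#' @export
mate_correlations <- function(ped, phen) {
  pairs <- mate_pairs(ped, phen)
  strata <- list(urban = pairs[pairs$habitat == "urban", ],
                 rural = pairs[pairs$habitat == "rural", ],
                 all = pairs)
  purrr::imap_dfr(strata, function(df, lab) {
    if (nrow(df) < 3) return(NULL)
    rr <- mate_correlation(df$female_lf, df$male_lf)
    tibble(habitat = lab, r = as.numeric(rr), n_pairs = attr(rr, "n_pairs"))
  })
}

#' Parent-offspring heritability table across methods and habitats
#'
#' Runs the midparent, father and mother regressions for each habitat
#' stratum (urban, rural, all), applying the (1 + r) assortative-mating
#' correction to the single-parent estimates with the stratum's mate
#' correlation.
#'
#' @inheritParams build_po_dataset
#' @param mate_r Named numeric vector of mate correlations per stratum
#'   (names among `"urban"`, `"rural"`, `"all"`); by default estimated from
#'   the data with [mate_correlations()]. Strata without an entry use 0.
#' @return An `h2_estimate` tibble, one row per method x habitat with at
#'   least 3 broods.
#' @export
po_heritability <- function(ped, phen, mate_r = NULL) {
  if (is.null(mate_r)) {
    mc <- mate_correlations(ped, phen)
    mate_r <- setNames(mc$r, mc$habitat)
  }
  rows <- list()
  for (mode in c("midparent", "father", "mother")) {
    ds_all <- build_po_dataset(ped, phen, mode)
    for (hab in c("rural", "urban", "all")) {
      ds <- if (hab == "all") ds_all else ds_all[ds_all$habitat == hab, ]
      if (nrow(ds) < 3) next
      rows[[paste(mode, hab)]] <- if (mode == "midparent") {
        midparent_h2(ds, habitat = hab)
      } else {
        r <- if (hab %in% names(mate_r)) unname(mate_r[[hab]]) else 0
        single_parent_h2(ds, r = r, habitat = hab)
      }
    }
  }
  if (!length(rows)) abort("No stratum had at least 3 broods.")
  new_h2_estimate(bind_rows(rows))
}
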