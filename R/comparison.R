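#' Compare two heritability estimates by z-score
#'
#' `z = (h2_i - h2_j) / sqrt(se_i^2 + se_j^2)` with a two-sided normal
#' p-value `2 (1 - Phi(|z|))`. Alongside the raw values, the reported pair
#' follows the convention of published comparison tables: `z_reported` is z
#' rounded to 2 decimals and `p_reported` is the two-sided p of the
#' *rounded* z, rounded to 4 decimals.
#'
#' @param e_i,e_j One-row data frames (e.g. [midparent_h2()] output) or
#'   lists with elements `h2` and `se` (`se > 0`).
#' @return A one-row tibble of class `h2_comparison`: `pair`, `z`, `p`,
#'   `z_reported`, `p_reported`.
#' @export
z_compare <- function(e_i, e_j) {
  gi <- extract_estimate(e_i)
  gj <- extract_estimate(e_j)
  if (gi$se <= 0 || gj$se <= 0) abort("Standard errors must be > 0.")
  z <- (gi$h2 - gj$h2) / sqrt(gi$se^2 + gj$se^2)
  zr <- round(z, 2)
  res <- tibble(
    pair = paste(gi$label, "vs", gj$label),
    z = z,
    p = 2 * pnorm(abs(z), lower.tail = FALSE),
    z_reported = zr,
    p_reported = round(2 * pnorm(abs(zr), lower.tail = FALSE), 4)
  )
  class(res) <- c("h2_comparison", class(tibble()))
  res
}

extract_estimate <- function(e) {
  if (is.data.frame(e)) {
    stopifnot(nrow(e) == 1)
    label <- if (all(c("method", "habitat") %in% names(e))) {
      paste0(e$method, "/", e$habitat)
    } else "estimate"
    list(h2 = e$h2, se = e$se, label = label)
  } else {
    list(h2 = e$h2, se = e$se, label = e$label %||% "estimate")
  }
}

#' All pairwise z-comparisons within an estimates table
#'
#' @param estimates An `h2_estimate` tibble ([po_heritability()] output or
#'   any data frame with `h2`, `se` and label columns `method`, `habitat`).
#' @param within Optional column name; only rows sharing a value of this
#'   column are compared (e.g. `"method"` to compare habitats within each
#'   regression type, mirroring the usual reporting layout).
#' @return An `h2_comparison` tibble, one row per compared pair.
#' @export
compare_h2 <- function(estimates, within = "method") {
  stopifnot(nrow(estimates) >= 2)
  groups <- if (!is.null(within) && within %in% names(estimates)) {
    split(seq_len(nrow(estimates)), estimates[[within]])
  } else {
    list(seq_len(nrow(estimates)))
  }
  out <- list()
  for (idx in groups) {
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    for (k in seq_len(ncol(cmb))) {
      out[[length(out) + 1]] <- z_compare(estimates[cmb[1, k], ],
                                          estimates[cmb[2, k], ])
    }
  }
  res <- bind_rows(out)
  class(res) <- c("h2_comparison", class(tibble()))
  res
}

#' One-way F-test of log-FID between habitats
#'
#' Fixed-effects one-way analysis of variance of log-FID on habitat
#' (urban vs rural), the standard first-pass check that urban birds tolerate
#' closer approach. Numerator df is 1.
#'
#' @param phen A phenotype tibble with `log_fid` and `habitat` (both
#'   habitats present, >= 2 individuals each).
#' @return A one-row tibble: `statistic` (F), `df`, `df_residual`,
#'   `p_value`.
#' @export
habitat_fid_test <- function(phen) {
  dat <- phen[phen$habitat %in% c("urban", "rural"), ]
  tab <- table(dat$habitat)[c("urban", "rural")]
  if (anyNA(tab) || any(tab < 2)) {
    abort("Both habitats must be present with at least 2 individuals each.")
  }
  fit <- lm(log_fid ~ habitat, data = dat)
  av <- anova(fit)
  tibble(statistic = av[["F value"]][1], df = av[["Df"]][1],
         df_residual = av[["Df"]][2], p_value = av[["Pr(>F)"]][1])
}
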