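#' Validate and order a pedigree
#'
#' Checks a table of individuals for structural soundness and returns it
#' topologically sorted so that every parent precedes all of its offspring.
#' The relative input order is preserved among individuals whose ordering is
#' otherwise unconstrained, so repeated validation is idempotent.
#'
#' Unknown parents may be encoded as `NA`, the empty string, `"0"` or `"NA"`;
#' all are normalised to `NA`. Founders are individuals with both parents
#' unknown and are assumed unrelated and non-inbred (base population).
#' Individuals with exactly one known parent are allowed, as happens when an
#' unringed mate is identified only through shared offspring.
#'
#' @param records A data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"female"`, `"male"` or `"unknown"`) and `habitat` (`"urban"`,
#'   `"rural"` or `"unknown"`). Missing `sex`/`habitat` columns are filled
#'   with `"unknown"`.
#'
#' @return A tibble of class `fid_pedigree` with columns `id`, `sire`, `dam`,
#'   `sex`, `habitat` and `generation` (0 for founders, otherwise one more
#'   than the deepest known parent), sorted parents-before-offspring.
#'
#' @details Validation fails on: duplicate or empty ids, self-parentage,
#'   a parent id that is referenced but absent from the table, the same id
#'   used both as a sire and as a dam, a recorded female used as sire (or
#'   male as dam), and parentage cycles.
#'
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   id = c("o1", "f1", "f2"),
#'   sire = c("f1", NA, NA),
#'   dam = c("f2", NA, NA),
#'   sex = c("unknown", "male", "female")
#' ))
#' ped$generation
#' @export
validate_pedigree <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame.")
  }
  need <- c("id", "sire", "dam")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` lacks required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  ped <- as_tibble(records)
  ped$id <- as.character(ped$id)
  ped$sire <- normalise_parent(ped$sire)
  ped$dam <- normalise_parent(ped$dam)
  ped$sex <- normalise_level(
    if ("sex" %in% names(ped)) ped$sex else "unknown",
    SEX_LEVELS, "sex", nrow(ped))
  ped$habitat <- normalise_level(
    if ("habitat" %in% names(ped)) ped$habitat else "unknown",
    HABITAT_LEVELS, "habitat", nrow(ped))
  ped <- ped[, c("id", "sire", "dam", "sex", "habitat")]

  if (anyNA(ped$id) || any(ped$id == "")) abort("Empty or missing individual id.")
  dup <- unique(ped$id[duplicated(ped$id)])
  if (length(dup)) {
    abort(paste0("Duplicate id(s) in pedigree: ", paste(dup, collapse = ", "), "."))
  }
  self <- ped$id == ped$sire | ped$id == ped$dam
  if (any(self, na.rm = TRUE)) {
    abort(paste0("Self-parentage for id(s): ",
                 paste(ped$id[which(self)], collapse = ", "), "."))
  }
  referenced <- unique(c(ped$sire, ped$dam))
  referenced <- referenced[!is.na(referenced)]
  absent <- setdiff(referenced, ped$id)
  if (length(absent)) {
    abort(paste0("Parent id(s) referenced but absent: ",
                 paste(absent, collapse = ", "), "."))
  }
  sires <- unique(ped$sire[!is.na(ped$sire)])
  dams <- unique(ped$dam[!is.na(ped$dam)])
  both <- intersect(sires, dams)
  if (length(both)) {
    abort(paste0("Id(s) used as both sire and dam: ",
                 paste(both, collapse = ", "), "."))
  }
  sex_of <- setNames(ped$sex, ped$id)
  bad_sire <- sires[sex_of[sires] == "female"]
  bad_dam <- dams[sex_of[dams] == "male"]
  if (length(bad_sire) || length(bad_dam)) {
    abort(paste0("Sex inconsistent with parental role for id(s): ",
                 paste(c(bad_sire, bad_dam), collapse = ", "), "."))
  }

  # Layered topological sort (Kahn by generation sweeps); input order is
  # preserved within each sweep, so the result is stable.
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  generation <- rep(NA_integer_, n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining)) {
    s_ok <- is.na(ped$sire[remaining]) | placed[ifelse(is.na(si[remaining]), 1L, si[remaining])] & !is.na(si[remaining])
    d_ok <- is.na(ped$dam[remaining]) | placed[ifelse(is.na(di[remaining]), 1L, di[remaining])] & !is.na(di[remaining])
    ready <- remaining[s_ok & d_ok]
    if (!length(ready)) {
      abort(paste0("Parentage cycle detected involving id(s): ",
                   paste(ped$id[remaining], collapse = ", "), "."))
    }
    pg_s <- ifelse(is.na(si[ready]), -1L, generation[ifelse(is.na(si[ready]), 1L, si[ready])])
    pg_d <- ifelse(is.na(di[ready]), -1L, generation[ifelse(is.na(di[ready]), 1L, di[ready])])
    generation[ready] <- pmax(pg_s, pg_d, -1L) + 1L
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- remaining[!(s_ok & d_ok)]
  }
  ped <- ped[order_out, ]
  ped$generation <- generation[order_out]
  new_pedigree(ped)
}

new_pedigree <- function(x) {
  class(x) <- c("fid_pedigree", class(tibble()))
  x
}

#' @export
print.fid_pedigree <- function(x, ...) {
  cat(sprintf("<fid_pedigree> %d individuals, %d founder(s), %d generation layer(s)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam)),
              max(x$generation) + 1L))
  NextMethod()
}

normalise_parent <- function(x) {
  x <- as.character(x)
  x[x %in% UNKNOWN_PARENT] <- NA_character_
  x
}

normalise_level <- function(x, levels, what, n) {
  x <- as.character(x)
  if (length(x) == 1 && n > 1) x <- rep(x, n)
  x[is.na(x) | x == ""] <- "unknown"
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    abort(paste0("Invalid ", what, " value(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(levels, collapse = "/"), ")."))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_pedigree <- function(ped) {
  if (!inherits(ped, "fid_pedigree")) {
    abort("Expected a validated pedigree; run `validate_pedigree()` first.")
  }
  invisible(ped)
}
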