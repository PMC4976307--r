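#' Read a pedigree from a tab-separated file
#'
#' Expects a header with columns `id`, `sire`, `dam` and optionally `sex`
#' and `habitat`. The values `""`, `"0"` and `"NA"` in the parent columns
#' all denote an unknown parent. The result is validated and topologically
#' sorted by [validate_pedigree()].
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A validated pedigree tibble.
#' @export
read_pedigree_file <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(c("id", "sire", "dam"), names(df))
  if (length(missing_cols)) {
    abort(paste0("Pedigree file lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  validate_pedigree(df)
}

#' Write a pedigree to a tab-separated file
#'
#' Unknown parents are written as `"0"`, the conventional pedigree-file
#' sentinel. Reading the file back with [read_pedigree_file()] reproduces
#' the pedigree exactly.
#'
#' @param ped A validated pedigree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  assert_pedigree(ped)
  out <- ped[, c("id", "sire", "dam", "sex", "habitat")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read flight initiation distances from a CSV file
#'
#' Expects a header with columns `id` and `fid_m` (FID in meters, > 0) and
#' optional `sex` and `habitat`. Repeated measures (repeated `id` rows) are
#' collapsed to the arithmetic mean of `fid_m` on the meter scale *before*
#' the log transform, following the field convention of using one FID per
#' individual or the mean of its measures; `n_measures` records how many
#' rows were collapsed. Rows are returned sorted by `id`, so the result is
#' invariant to the input row order.
#'
#' @param path Path to a CSV file.
#' @return A phenotype tibble: `id`, `fid_m`, `log_fid` (natural log
#'   meters), `sex`, `habitat`, `n_measures`; one row per individual.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing_cols <- setdiff(c("id", "fid_m"), names(df))
  if (length(missing_cols)) {
    abort(paste0("Phenotype file lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  df$id <- as.character(df$id)
  if (anyNA(df$id)) abort("Phenotype file has rows with missing id.")
  df$fid_m <- as.numeric(df$fid_m)
  bad <- which(!is.finite(df$fid_m) | df$fid_m <= 0)
  if (length(bad)) {
    abort(paste0("Non-positive or missing fid_m on row(s): ",
                 paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  if (!"habitat" %in% names(df)) df$habitat <- "unknown"
  df$sex <- normalise_level(df$sex, SEX_LEVELS, "sex", nrow(df))
  df$habitat <- normalise_level(df$habitat, HABITAT_LEVELS, "habitat", nrow(df))
  df |>
    group_by(.data$id) |>
    summarise(fid_m = mean(.data$fid_m), sex = first(.data$sex),
              habitat = first(.data$habitat), n_measures = dplyr::n(),
              .groups = "drop") |>
    mutate(log_fid = log(.data$fid_m)) |>
    select("id", "fid_m", "log_fid", "sex", "habitat", "n_measures") |>
    arrange(.data$id)
}

#' Write a phenotype table to CSV
#'
#' @param phen A phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  readr::write_csv(phen, path, progress = FALSE)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Writes the pedigree (TSV), the phenotypes (CSV) and a truth file (JSON:
#' generating parameters, seed, and per-individual true breeding values)
#' into a directory, so a simulated study can be re-ingested through the
#' ordinary file readers.
#'
#' @param study A `fid_study` from [simulate_fid_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "fid_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.json"))
  write_pedigree(study$pedigree, paths[["pedigree"]])
  write_phenotypes(study$phenotypes, paths[["phenotypes"]])
  truth <- study$truth
  truth$breeding_values <- setNames(as.list(study$breeding_values$bv),
                                    study$breeding_values$id)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a long-format family table of raw parent/offspring FIDs
#'
#' Reader for deposited raw parent-offspring data laid out one measure per
#' row: columns `family` (brood identifier), `role` (`"father"`,
#' `"mother"` or `"offspring"`) and `fid_m` (meters, > 0), with an optional
#' `habitat` column. Builds a regression-ready brood table directly:
#' offspring values are averaged within family (full-sib averaging) and
#' parental values logged, so [midparent_h2()] / [single_parent_h2()] can
#' be applied without a pedigree.
#'
#' @param path Path to a CSV file.
#' @param mode Which parental value to construct; as in
#'   [build_po_dataset()].
#' @return A `po_dataset` tibble (families lacking the required parent
#'   role(s) or any offspring are dropped).
#' @export
read_parent_offspring <- function(path, mode = c("midparent", "father", "mother")) {
  mode <- match.arg(mode)
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing_cols <- setdiff(c("family", "role", "fid_m"), names(df))
  if (length(missing_cols)) {
    abort(paste0("Family file lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  bad_role <- setdiff(unique(df$role), c("father", "mother", "offspring"))
  if (length(bad_role)) {
    abort(paste0("Invalid role(s): ", paste(bad_role, collapse = ", "), "."))
  }
  if (any(df$fid_m <= 0)) abort("All fid_m values must be > 0.")
  if (!"habitat" %in% names(df)) df$habitat <- "unknown"
  ds <- df |>
    group_by(.data$family) |>
    summarise(
      father_lf = if (any(.data$role == "father"))
        log(mean(.data$fid_m[.data$role == "father"])) else NA_real_,
      mother_lf = if (any(.data$role == "mother"))
        log(mean(.data$fid_m[.data$role == "mother"])) else NA_real_,
      offspring_value = if (any(.data$role == "offspring"))
        mean(log(.data$fid_m[.data$role == "offspring"])) else NA_real_,
      brood_size = sum(.data$role == "offspring"),
      habitat = names(sort(table(.data$habitat[.data$role == "offspring"]),
                           decreasing = TRUE))[1] %||% "unknown",
      .groups = "drop"
    ) |>
    mutate(parent_value = switch(mode,
      midparent = (.data$father_lf + .data$mother_lf) / 2,
      father = .data$father_lf,
      mother = .data$mother_lf
    ), mode = mode) |>
    filter(!is.na(.data$parent_value), !is.na(.data$offspring_value)) |>
    select("family", "parent_value", "offspring_value", "brood_size",
           "habitat", "mode")
  if (nrow(ds) == 0) abort("No usable families in file.")
  class(ds) <- c("po_dataset", class(ds))
  ds
}
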