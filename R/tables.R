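#' Documented IgG-FcgR affinities
#'
#' Consensus published surface-plasmon-resonance association constants for
#' the four human IgG subclasses against the six FcgR variants screened in
#' the CHO panel. The `ka_se` column is a constructed stand-in (10% of the
#' value) because per-interaction standard errors are not available here;
#' with the prior clipping rules this floors the prior interquartile range
#' at 1e5 for all but the strongest interactions. A `ka` of 0 encodes a
#' recorded non-binder (e.g. IgG2-FcgRI) and enters prior construction
#' through the clipping rule rather than being excluded, so such
#' interactions remain estimable.
#'
#' @return tibble with columns `ligand`, `receptor`, `ka`, `ka_se`.
#' @export
documented_affinities <- function() {
  read_affinities(system.file("extdata", "affinities_documented_synthetic_se.csv",
                              package = "fcbindr", mustWork = TRUE))
}

#' Effector-cell FcgR abundance profiles
#'
#' Per-cell-type receptor numbers (receptors/cell, geometric-mean scale) for
#' classical monocytes (cMO), non-classical monocytes (ncMO) and neutrophils
#' (Neu). Constructed plausible values (synthetic stand-in for quantitative
#' flow-cytometry receptor quantitation), chosen so that monocytes are
#' FcgRI-rich and neutrophils FcgRIIA-dominated.
#'
#' @return tibble with columns `cell`, `receptor`, `rtot`.
#' @export
effector_cell_profiles <- function() {
  path <- system.file("extdata", "effector_profiles_synthetic.csv",
                      package = "fcbindr", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a tidy affinity table
#'
#' @param path CSV with header columns `ligand`, `receptor`, `ka` and
#'   optionally `ka_se` (1/M; scientific notation accepted).
#' @return validated tibble.
#' @export
read_affinities <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ligand", "receptor", "ka")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    rlang::abort(paste0("affinity table missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(tbl$ka)) || any(tbl$ka < 0)) {
    rlang::abort("affinities must be finite and >= 0")
  }
  tbl
}

#' Read a receptor-expression replicate table
#'
#' @param path CSV with columns `receptor` (CHO line label), `replicate`,
#'   `rtot` (receptors/cell).
#' @return validated tibble.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("receptor", "replicate", "rtot"), names(tbl))
  if (length(miss)) {
    rlang::abort(paste0("expression table missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (any(tbl$rtot <= 0)) rlang::abort("rtot must be > 0")
  tbl
}

#' Read a replicate-level binding measurement table
#'
#' Validates the tidy screen layout: one row per technical replicate with
#' the batch day, receptor variant (CHO line), complex valency, the IgG
#' subclass pair (`"IgG1/IgG2"` style), the composition fraction of the
#' first pair member, the replicate index and the normalized fluorescence
#' readout. Warns when the per-day geometric means deviate from 1, the
#' convention the screen is normalized to.
#'
#' @param path CSV file.
#' @param receptors optional character vector of known receptor labels;
#'   unknown labels are rejected when supplied.
#' @return validated tibble.
#' @export
read_measurements <- function(path, receptors = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_measurements(tbl, receptors = receptors)
}

#' @rdname read_measurements
#' @param tbl an in-memory measurement table.
#' @export
validate_measurements <- function(tbl, receptors = NULL) {
  need <- c("day", "receptor", "valency", "pair", "frac1", "replicate", "rfu")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    rlang::abort(paste0("measurement table missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(tbl$rfu) | tbl$rfu <= 0)
  if (length(bad)) {
    rlang::abort(sprintf("nonpositive rfu at row(s): %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(tbl$frac1 < 0 | tbl$frac1 > 1)) {
    rlang::abort("frac1 must lie in [0, 1]")
  }
  if (!is.null(receptors)) {
    unk <- setdiff(unique(tbl$receptor), receptors)
    if (length(unk)) {
      rlang::abort(paste0("unknown receptor label(s): ",
                          paste(unk, collapse = ", ")))
    }
  }
  gm <- tapply(log(tbl$rfu), tbl$day, mean)
  if (any(abs(gm) > 1e-6)) {
    rlang::warn("per-day geometric means differ from 1; consider normalize_by_day()")
  }
  tibble::as_tibble(tbl)
}

#' Normalize a measurement table to per-day geometric mean 1
#'
#' @param tbl measurement table with `day` and `rfu` columns.
#' @return tibble with `rfu` rescaled so each day's geometric mean is 1.
#' @export
normalize_by_day <- function(tbl) {
  tbl |>
    dplyr::group_by(.data$day) |>
    dplyr::mutate(rfu = .data$rfu / exp(mean(log(.data$rfu)))) |>
    dplyr::ungroup()
}

#' Read an in vivo depletion record table
#'
#' @param path CSV with columns `treatment` (IgG subclass), `experiment`,
#'   `y` (observed fraction of target cells depleted, in \[0, 1\]).
#' @return validated tibble.
#' @export
read_depletion <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("treatment", "experiment", "y"), names(tbl))
  if (length(miss)) {
    rlang::abort(paste0("depletion table missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (any(tbl$y < 0 | tbl$y > 1)) rlang::abort("y must lie in [0, 1]")
  tbl
}

# split "IgG1/IgG2" pair labels into two members
.split_pair <- function(pair) {
  parts <- strsplit(pair, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    rlang::abort("pair labels must be of the form \"IgG1/IgG2\"")
  }
  list(first = vapply(parts, `[`, "", 1L),
       second = vapply(parts, `[`, "", 2L))
}
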