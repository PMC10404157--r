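#' The six FcgR variants of the CHO screening panel
#' @export
screen_receptors <- c("FcgRI", "FcgRIIA-131H", "FcgRIIA-131R",
                      "FcgRIIB-232I", "FcgRIIIA-158F", "FcgRIIIA-158V")

#' The four human IgG subclasses
#' @export
igg_subclasses <- c("IgG1", "IgG2", "IgG3", "IgG4")

#' Canonical composition series of the mixture screen
#'
#' Fractions of the first pair member: 100%, 90%, two-thirds, one-third,
#' 10%, 0%.
#' @export
composition_series <- c(1, 0.9, 2 / 3, 1 / 3, 0.1, 0)

#' Full factorial design of the mixture binding screen
#'
#' Every combination of receptor variant, complex valency, unordered IgG
#' subclass pair and composition level: 6 x 2 x 6 x 6 = 432 condition rows.
#' Pure endpoints are counted per pair (not deduplicated), mirroring how the
#' screen was laid out.
#'
#' @param receptors receptor variant labels.
#' @param subclasses IgG subclass labels (pairs are all unordered pairs).
#' @param valencies complex valencies.
#' @param fractions composition series (fraction of the first pair member).
#' @return tibble (`receptor`, `valency`, `pair`, `frac1`).
#' @export
generate_design <- function(receptors = screen_receptors,
                            subclasses = igg_subclasses,
                            valencies = c(4, 33),
                            fractions = composition_series) {
  pairs <- utils::combn(subclasses, 2)
  tidyr::expand_grid(
    receptor = receptors,
    valency = valencies,
    pair = paste0(pairs[1, ], "/", pairs[2, ]),
    frac1 = fractions
  )
}

#' Ground truth for synthetic binding screens
#'
#' The generating parameter set recorded alongside every simulated dataset:
#' true affinities (documented values with the non-binder clip applied, so
#' synthetic screens resemble the study's dynamic range), true per-line
#' receptor expression, effective valencies equal to the nominal ones, the
#' default crosslinking constant, per-day batch scales (drawn log-normally
#' around 0.3, placing raw fluorescence in the instrument's working range),
#' and the technical noise level.
#'
#' @param seed integer seed (controls the batch-scale draw).
#' @param days number of measurement days/batches.
#' @param noise_cv technical replicate coefficient of variation.
#' @param affinities documented affinity table.
#' @param expression named per-line true receptor numbers.
#' @param valencies nominal valencies.
#' @return list of class `fcr_ground_truth`.
#' @export
binding_ground_truth <- function(seed = 1L, days = 3L, noise_cv = 0.2,
                                 affinities = documented_affinities(),
                                 expression = c(
                                   "FcgRI" = 1.5e5, "FcgRIIA-131H" = 8e5,
                                   "FcgRIIA-131R" = 5e5, "FcgRIIB-232I" = 2e5,
                                   "FcgRIIIA-158F" = 3e5,
                                   "FcgRIIIA-158V" = 2.5e5),
                                 valencies = c(4, 33)) {
  set.seed(seed)
  truth_ka <- dplyr::mutate(affinities, ka = pmax(.data$ka, 1e4))
  structure(list(
    affinity = truth_ka,
    expression = expression,
    f = stats::setNames(as.numeric(valencies), valencies),
    kx_star = default_kx_star,
    batch_scale = stats::setNames(
      exp(stats::rnorm(days, log(0.3), 0.3)), paste0("d", seq_len(days))),
    noise_cv = noise_cv,
    seed = seed
  ), class = "fcr_ground_truth")
}

# noiseless model-predicted Lbound for each design row under a ground truth
.design_lbound <- function(truth, design, l0 = 1e-9) {
  ka <- affinity_matrix(truth$affinity)
  pm <- .split_pair(design$pair)
  ri <- match(design$receptor, colnames(ka))
  if (anyNA(ri)) rlang::abort("design receptor absent from truth affinities")
  ka_eff <- design$frac1 * ka[cbind(match(pm$first, rownames(ka)), ri)] +
    (1 - design$frac1) * ka[cbind(match(pm$second, rownames(ka)), ri)]
  rtot <- truth$expression[design$receptor]
  f <- truth$f[as.character(design$valency)]
  s <- .solve_s_vec(ka_eff, rtot, l0, f, truth$kx_star)
  unname(l0 / truth$kx_star * (s^f - 1))
}

#' Forward-simulate a replicate-level binding screen
#'
#' Conditions are randomized across measurement days, predicted bound
#' complexes computed from the ground truth, scaled by the day's batch
#' factor, perturbed by multiplicative log-normal technical noise with the
#' requested coefficient of variation, and finally normalized so each day's
#' geometric mean is 1 -- the structure of the flow-cytometry screen the
#' analysis assumes.
#'
#' @param truth a [binding_ground_truth()].
#' @param design design table from [generate_design()].
#' @param replicates technical replicates per condition.
#' @param noise_cv noise level (defaults to the truth's).
#' @param seed integer seed.
#' @param l0 complex concentration (M).
#' @return measurement tibble (`day`, `receptor`, `valency`, `pair`,
#'   `frac1`, `replicate`, `rfu`) carrying the ground truth in attribute
#'   `"ground_truth"`.
#' @export
simulate_binding_screen <- function(truth, design = generate_design(),
                                    replicates = 3L,
                                    noise_cv = truth$noise_cv, seed = 1L,
                                    l0 = 1e-9) {
  set.seed(seed)
  days <- names(truth$batch_scale)
  cond_day <- sample(rep_len(days, nrow(design)))
  lbound <- .design_lbound(truth, design, l0 = l0)
  out <- design
  out$day <- cond_day
  out$lbound <- lbound
  out <- tidyr::expand_grid(out, replicate = seq_len(replicates))
  sigma <- sqrt(log(1 + noise_cv^2))
  eps <- if (noise_cv > 0) stats::rnorm(nrow(out), 0, sigma) else 0
  out$rfu <- unname(truth$batch_scale[out$day]) * out$lbound * exp(eps)
  out <- normalize_by_day(out)
  out <- dplyr::select(out, "day", "receptor", "valency", "pair", "frac1",
                       "replicate", "rfu")
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate receptor-expression quantitation replicates
#'
#' Log-normal replicates around the true per-line receptor numbers,
#' emulating bead-calibrated receptor quantitation across experiments.
#'
#' @param truth a [binding_ground_truth()].
#' @param n replicates per line (>= 2).
#' @param cv replicate coefficient of variation.
#' @param seed integer seed.
#' @return tibble (`receptor`, `replicate`, `rtot`).
#' @export
simulate_expression_replicates <- function(truth, n = 4L, cv = 0.15,
                                           seed = 1L) {
  if (n < 2) rlang::abort("need n >= 2 replicates")
  set.seed(seed)
  sigma <- sqrt(log(1 + cv^2))
  tidyr::expand_grid(receptor = names(truth$expression),
                     replicate = seq_len(n)) |>
    dplyr::mutate(rtot = truth$expression[.data$receptor] *
                    exp(stats::rnorm(dplyr::n(), 0, sigma)))
}

#' Default ground-truth effector-cell weights
#'
#' Per-cell-type clearance potencies used by the synthetic depletion study,
#' chosen so that (a) classical monocytes are the dominant effector, the
#' regression's qualitative finding in vivo, and (b) predicted depletion of
#' strong subclasses falls in the experimentally observed 60-90% range
#' under the default activities. Units: inverse activity.
#'
#' @export
default_cell_weights <- function() {
  c(cMO = 6e-5, ncMO = 1e-5, Neu = 2e-5)
}

#' Simulate a humanized-mouse-style depletion study
#'
#' Per-mouse depletion fractions drawn from a beta distribution centered on
#' the model-predicted depletion for each treatment, with a concentration
#' parameter controlling the (large) experiment-to-experiment spread.
#'
#' @param truth_weights named true cell-type weights (>= 0).
#' @param profiles cell-type receptor table.
#' @param affinities tidy affinity table for the binding predictions.
#' @param subclasses treatments to simulate.
#' @param n_mice mice (experiments) per treatment.
#' @param concentration beta concentration; larger = less noisy.
#' @param seed integer seed.
#' @param spec an [ic_spec()].
#' @return depletion tibble (`treatment`, `experiment`, `y`) with the true
#'   weights and noiseless predictions in attribute `"ground_truth"`.
#' @export
simulate_depletion_study <- function(truth_weights = default_cell_weights(),
                                     profiles = effector_cell_profiles(),
                                     affinities = NULL,
                                     subclasses = igg_subclasses,
                                     n_mice = 6L, concentration = 30,
                                     seed = 1L, spec = ic_spec()) {
  if (any(truth_weights < 0)) rlang::abort("weights must be >= 0")
  if (is.null(affinities)) {
    affinities <- dplyr::mutate(documented_affinities(),
                                ka = pmax(.data$ka, 1e4))
  }
  acts <- cell_activities(profiles, affinities, treatments = subclasses,
                          spec = spec)
  pred <- predict_depletion(acts, truth_weights)
  set.seed(seed)
  out <- tidyr::expand_grid(treatment = subclasses,
                            experiment = seq_len(n_mice)) |>
    dplyr::left_join(pred, by = "treatment") |>
    dplyr::mutate(
      m = pmin(pmax(.data$pred, 1e-4), 1 - 1e-4),
      y = stats::rbeta(dplyr::n(), .data$m * concentration,
                       (1 - .data$m) * concentration)) |>
    dplyr::select("treatment", "experiment", "y")
  attr(out, "ground_truth") <- list(weights = truth_weights,
                                    predictions = pred, seed = seed,
                                    concentration = concentration)
  out
}

#' Write a ground-truth manifest as JSON
#'
#' @param truth a [binding_ground_truth()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  manifest <- list(
    affinity = truth$affinity,
    expression = as.list(truth$expression),
    f = as.list(truth$f),
    kx_star = truth$kx_star,
    batch_scale = as.list(truth$batch_scale),
    noise_cv = truth$noise_cv,
    seed = truth$seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
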