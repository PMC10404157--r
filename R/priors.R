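#' Log-normal parameters from mode and interquartile range
#'
#' Solves for the `(mu, sigma)` of a log-normal distribution whose mode is
#' `mode` and whose interquartile range is `iqr`:
#' \eqn{e^{\mu - \sigma^2} = mode} and
#' \eqn{e^{\mu + z\sigma} - e^{\mu - z\sigma} = iqr} with `z = qnorm(0.75)`.
#' Substituting the first equation leaves one strictly increasing equation
#' in `sigma`, solved numerically to 1e-12.
#'
#' This is how documented affinities with standard errors become priors:
#' the documented value is the prior mode and its standard error the prior
#' IQR, after clipping (`mode >= 1e4`, `iqr >= 1e5`) so that recorded
#' non-binders receive a wide, estimable prior instead of being excluded.
#'
#' @param mode,iqr positive scalars.
#' @return named numeric vector `c(mu, sigma)`.
#' @examples
#' p <- lognormal_from_mode_iqr(1e6, 1e5)
#' exp(p[["mu"]] - p[["sigma"]]^2) # recovers the mode
#' @export
lognormal_from_mode_iqr <- function(mode, iqr) {
  if (mode <= 0 || iqr <= 0) rlang::abort("mode and iqr must be > 0")
  z <- stats::qnorm(0.75)
  # g(sigma) = mode * exp(sigma^2) * 2 sinh(z sigma) - iqr, increasing from 0
  g <- function(sigma) mode * exp(sigma^2) * 2 * sinh(z * sigma) - iqr
  upper <- 1
  while (g(upper) < 0 && upper < 50) upper <- upper * 2
  if (g(upper) < 0) rlang::abort("no positive-sigma solution in numeric range")
  sigma <- stats::uniroot(g, c(1e-12, upper), tol = 1e-14)$root
  c(mu = log(mode) + sigma^2, sigma = sigma)
}

#' Affinity prior with documented-value clipping
#'
#' @param ka documented association constant (1/M; 0 encodes non-binding).
#' @param se documented standard error.
#' @param clip_mode,clip_iqr clipping floors for the prior mode and IQR.
#' @return tibble row: documented value/SE, clipped mode/IQR, `mu`, `sigma`.
#' @export
affinity_prior <- function(ka, se, clip_mode = 1e4, clip_iqr = 1e5) {
  mode <- max(ka, clip_mode)
  iqr <- max(se, clip_iqr)
  p <- lognormal_from_mode_iqr(mode, iqr)
  tibble::tibble(documented_ka = ka, documented_se = se,
                 mode = mode, iqr = iqr,
                 mu = p[["mu"]], sigma = p[["sigma"]])
}

# log-normal MLE on replicate values, with a floor on sigma to guard
# degenerate (identical) replicate sets
.lognormal_mle <- function(x, sigma_floor = 0.01) {
  lx <- log(x)
  n <- length(x)
  c(mu = mean(lx), sigma = max(stats::sd(lx) * sqrt((n - 1) / n), sigma_floor))
}

#' Build the full prior set for the binding-screen model
#'
#' Assembles priors for every parameter of the screen posterior:
#' * affinity priors from the documented table via
#'   [lognormal_from_mode_iqr()] with the non-binder clipping rule;
#' * receptor-expression priors fit to measured per-line replicates by
#'   log-normal maximum likelihood (sigma floored at 0.01);
#' * effective-valency priors, one per nominal valency `v` in the design:
#'   log-normal with `mu = log(v)`, `sigma = 0.2`;
#' * a crosslinking-constant prior log-normal around 6.31e-13 with
#'   `sigma = 2`;
#' * weak priors for the per-day scale factors (`logN(0, 10)` on the scale
#'   linking model binding units to normalized RFU) and the shared
#'   log-normal measurement noise (`sigma ~ logN(log 0.2, 1)`).
#'
#' @param documented tidy affinity table (`ligand`, `receptor`, `ka`,
#'   `ka_se`).
#' @param expression_replicates tibble (`receptor`, `replicate`, `rtot`)
#'   with at least two replicates per line.
#' @param valencies nominal valencies present in the design.
#' @param clip_mode,clip_iqr affinity clipping constants.
#' @param kx_star_mode,kx_star_sigma crosslinking prior settings.
#' @return object of class `fcr_priors`.
#' @export
build_priors <- function(documented, expression_replicates,
                         valencies = c(4, 33),
                         clip_mode = 1e4, clip_iqr = 1e5,
                         kx_star_mode = default_kx_star,
                         kx_star_sigma = 2.0) {
  if (!"ka_se" %in% names(documented)) {
    rlang::abort("documented affinity table needs a ka_se column")
  }
  affinity <- documented |>
    dplyr::mutate(prior = purrr::map2(.data$ka, .data$ka_se, affinity_prior,
                                      clip_mode = clip_mode,
                                      clip_iqr = clip_iqr)) |>
    dplyr::select("ligand", "receptor", "prior") |>
    tidyr::unnest("prior")
  counts <- expression_replicates |> dplyr::count(.data$receptor)
  if (any(counts$n < 2)) {
    rlang::abort("need >= 2 expression replicates per receptor line")
  }
  expression <- expression_replicates |>
    dplyr::group_by(.data$receptor) |>
    dplyr::summarise(mu = .lognormal_mle(.data$rtot)[["mu"]],
                     sigma = .lognormal_mle(.data$rtot)[["sigma"]],
                     .groups = "drop")
  valency <- tibble::tibble(valency = sort(unique(valencies)),
                            mu = log(sort(unique(valencies))), sigma = 0.2)
  structure(list(
    affinity = affinity,
    expression = expression,
    valency = valency,
    kx_star = c(mu = log(kx_star_mode), sigma = kx_star_sigma),
    scale = c(mu = 0, sigma = 10),
    noise = c(mu = log(0.2), sigma = 1)
  ), class = "fcr_priors")
}

#' @export
print.fcr_priors <- function(x, ...) {
  cat("<fcr_priors>\n")
  cat("  affinity interactions:", nrow(x$affinity), "\n")
  cat("  receptor lines:", nrow(x$expression), "\n")
  cat("  valencies:", paste(x$valency$valency, collapse = ", "), "\n")
  cat(sprintf("  kx_star ~ logN(%.3f, %.2f)\n", x$kx_star[["mu"]],
              x$kx_star[["sigma"]]))
  invisible(x)
}
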