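#' Immune-complex specification for in vivo prediction
#'
#' The complexes driving effector responses in vivo are modeled as 4-valent
#' at 1 nM, the conditions used when linking receptor multimerization to
#' target-cell depletion; both are overridable.
#'
#' @param l0 complex concentration (M).
#' @param f effective valency.
#' @param kx_star crosslinking constant.
#' @export
ic_spec <- function(l0 = 1e-9, f = 4, kx_star = default_kx_star) {
  list(l0 = l0, f = f, kx_star = kx_star)
}

#' Signed receptor weights
#'
#' Activating receptors carry weight +1 and the inhibitory receptor
#' (FcgRIIB) weight -1; a cell's activity is the clipped signed sum of its
#' multimerized receptors.
#'
#' @param receptors character vector of receptor labels.
#' @return named numeric vector of +1/-1 weights.
#' @export
receptor_weights <- function(receptors) {
  stats::setNames(ifelse(grepl("IIB", receptors), -1, 1), receptors)
}

#' Antibody-driven activity of one effector cell
#'
#' \eqn{x_n = \max(\sum_i p_i R_{multi,i}, 0)}: the signed sum of
#' multimerized receptor amounts, clipped at zero so that engagement of the
#' inhibitory receptor alone yields no activity.
#'
#' @param rmulti_vector named multimerized-receptor amounts.
#' @param weights named +1/-1 receptor weights (defaults to
#'   [receptor_weights()] on the `rmulti_vector` names).
#' @return nonnegative scalar.
#' @export
cell_activity <- function(rmulti_vector, weights = NULL) {
  if (is.null(weights)) weights <- receptor_weights(names(rmulti_vector))
  if (!is.null(names(rmulti_vector)) && !is.null(names(weights))) {
    if (!setequal(names(rmulti_vector), names(weights))) {
      rlang::abort("receptor labels of rmulti and weights do not match")
    }
    weights <- weights[names(rmulti_vector)]
  } else if (length(rmulti_vector) != length(weights)) {
    rlang::abort("rmulti and weights lengths differ and labels are missing")
  }
  max(sum(weights * rmulti_vector), 0)
}

#' Model-predicted effector-cell activities per treatment
#'
#' Runs the multivalent binding model for each (treatment, cell type)
#' combination: single-subclass complexes per [ic_spec()] against the
#' cell's full receptor complement, followed by the signed, clipped
#' receptor-weighted sum of multimerized receptors.
#'
#' @param profiles cell-type receptor table (`cell`, `receptor`, `rtot`).
#' @param affinities tidy affinity table (`ligand`, `receptor`, `ka`).
#' @param treatments IgG subclass labels to model (default: all ligands in
#'   `affinities`).
#' @param spec an [ic_spec()].
#' @return tibble (`treatment`, `cell`, `activity`).
#' @export
cell_activities <- function(profiles, affinities, treatments = NULL,
                            spec = ic_spec()) {
  treatments <- treatments %||% unique(affinities$ligand)
  missing_t <- setdiff(treatments, unique(affinities$ligand))
  if (length(missing_t)) {
    rlang::abort(paste0("treatment(s) absent from affinity set: ",
                        paste(missing_t, collapse = ", ")))
  }
  cells <- unique(profiles$cell)
  grid <- tidyr::expand_grid(treatment = treatments, cell = cells)
  grid$activity <- purrr::pmap_dbl(grid, function(treatment, cell) {
    prof <- dplyr::filter(profiles, .data$cell == !!cell)
    ka_tbl <- affinities |>
      dplyr::filter(.data$ligand == treatment,
                    .data$receptor %in% prof$receptor)
    ka <- matrix(ka_tbl$ka[match(prof$receptor, ka_tbl$receptor)], nrow = 1,
                 dimnames = list(treatment, prof$receptor))
    eq <- solve_equilibrium(
      receptor_pool(cell, stats::setNames(prof$rtot, prof$receptor)),
      complex_mixture(spec$l0, spec$f, 1, spec$kx_star), ka)
    cell_activity(stats::setNames(eq$receptors$rmulti, eq$receptors$receptor))
  })
  grid
}

#' Predicted target-cell depletion from cell activities
#'
#' Survival-style link: given the weighted total activity
#' \eqn{X = \sum_n w_n x_n}, predicted depletion is the exponential CDF
#' \eqn{\hat y = 1 - e^{-X}}, bounded in \[0, 1) and approaching 1 as the
#' activity grows.
#'
#' @param activities either a named numeric vector of per-cell activities
#'   (returns a scalar) or a tibble from [cell_activities()] (returns one
#'   prediction per treatment).
#' @param cell_weights named nonnegative per-cell-type weights.
#' @return scalar or tibble (`treatment`, `linear_predictor`, `pred`).
#' @export
predict_depletion <- function(activities, cell_weights) {
  if (any(cell_weights < 0)) rlang::abort("cell weights must be >= 0")
  if (is.data.frame(activities)) {
    out <- activities |>
      dplyr::mutate(w = cell_weights[.data$cell]) |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(linear_predictor = sum(.data$w * .data$activity),
                       .groups = "drop") |>
      dplyr::mutate(pred = 1 - exp(-.data$linear_predictor))
    return(out)
  }
  w <- if (!is.null(names(activities))) cell_weights[names(activities)]
       else cell_weights
  x <- sum(w * activities)
  stopifnot(x >= 0)
  1 - exp(-x)
}

#' Fit cell-type weights against in vivo depletion records
#'
#' Bayesian regression of observed target-cell depletion on model-predicted
#' effector-cell activities. Weights are constrained positive through
#' log-normal priors centered so that a-priori total activity is of order
#' one; observations follow a beta likelihood centered on the exponential-CDF
#' prediction with a fitted concentration parameter (depletion fractions are
#' bounded and show large experiment-to-experiment spread). MAP
#' initialization plus adaptive Metropolis sampling; deterministic given the
#' seed.
#'
#' @param records depletion table (`treatment`, `experiment`, `y`).
#' @param profiles cell-type receptor table.
#' @param affinity_set tidy affinity table used for the binding predictions.
#' @param spec an [ic_spec()].
#' @param chains,draws,warmup,thin,seed MCMC settings.
#' @return object of class `fcr_depletion_fit` with posterior draws over
#'   log weights and the beta concentration; `tidy()` summarises weights,
#'   `glance()` the diagnostics, [cell_type_effects()] the per-(treatment,
#'   cell) effects.
#' @export
fit_depletion_weights <- function(records, profiles, affinity_set,
                                  spec = ic_spec(), chains = 2L,
                                  draws = 1000L, warmup = 1000L, thin = 2L,
                                  seed = 1L) {
  acts <- cell_activities(profiles, affinity_set,
                          treatments = unique(records$treatment),
                          spec = spec)
  cells <- unique(profiles$cell)
  xmat <- acts |>
    tidyr::pivot_wider(names_from = "cell", values_from = "activity") |>
    tibble::column_to_rownames("treatment") |>
    as.matrix()
  xmat <- xmat[, cells, drop = FALSE]
  ti <- match(records$treatment, rownames(xmat))
  y <- pmin(pmax(records$y, 1e-6), 1 - 1e-6)

  # weight prior centered a couple of log units below the scale at which
  # total activity would reach ~63% depletion: weakly-identified cell types
  # shrink toward small effects instead of inflating toward large ones
  pos <- xmat[xmat > 0]
  w_mu <- if (length(pos)) -log(length(cells) * mean(pos)) - 2 else 0
  d <- length(cells) + 1L
  prior_mu <- c(rep(w_mu, length(cells)), log(10))
  prior_sd <- c(rep(3, length(cells)), 1.5)

  lp_fun <- function(par) {
    w <- exp(par[seq_along(cells)])
    conc <- exp(par[d])
    lin <- drop(xmat %*% w)[ti]
    m <- pmin(pmax(1 - exp(-lin), 1e-6), 1 - 1e-6)
    ll <- sum(stats::dbeta(y, m * conc, (1 - m) * conc, log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dnorm(par, prior_mu, prior_sd, log = TRUE))
  }

  opt <- stats::optim(prior_mu, function(p) -lp_fun(p), method = "L-BFGS-B",
                      control = list(maxit = 500))
  hess <- stats::optimHess(opt$par, function(p) -lp_fun(p))
  ev <- eigen(hess, symmetric = TRUE)
  vals <- pmax(ev$values, max(abs(ev$values)) * 1e-8)
  cov0 <- ev$vectors %*% diag(1 / vals, d) %*% t(ev$vectors)

  chain_draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ci in seq_len(chains)) {
    set.seed(seed + ci - 1L)
    jit <- drop(stats::rnorm(d) %*% chol(cov0 + diag(1e-12, d))) * 0.1
    res <- .amh(lp_fun, opt$par + jit, cov0, warmup, draws, thin,
                center = opt$par)
    chain_draws[[ci]] <- res$draws
    accept[ci] <- res$accept
  }
  dmat <- do.call(rbind, chain_draws)
  colnames(dmat) <- c(paste0("logw[", cells, "]"), "logconc")
  structure(list(
    draws = dmat, cells = cells, activities = xmat,
    rhat = stats::setNames(.split_rhat(chain_draws), colnames(dmat)),
    accept = accept, records = tibble::as_tibble(records),
    spec = spec, seed = seed, chains = chains
  ), class = "fcr_depletion_fit")
}

#' @export
print.fcr_depletion_fit <- function(x, ...) {
  cat("<fcr_depletion_fit>", length(x$cells), "cell types;",
      nrow(x$draws), "draws\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_depletion_weights
#' @param x an `fcr_depletion_fit`.
#' @param ... unused.
#' @exportS3Method
tidy.fcr_depletion_fit <- function(x, ...) {
  wi <- seq_along(x$cells)
  q <- apply(exp(x$draws[, wi, drop = FALSE]), 2, stats::quantile,
             probs = c(0.25, 0.5, 0.75))
  tibble::tibble(cell = x$cells, weight_median = q[2, ],
                 weight_q25 = q[1, ], weight_q75 = q[3, ],
                 rhat = unname(x$rhat[wi]))
}

#' @rdname fit_depletion_weights
#' @exportS3Method
glance.fcr_depletion_fit <- function(x, ...) {
  tibble::tibble(cells = length(x$cells), draws = nrow(x$draws),
                 chains = x$chains, accept = mean(x$accept),
                 max_rhat = max(x$rhat))
}

#' Predicted depletion per treatment at the posterior median weights
#'
#' @param fit an `fcr_depletion_fit`.
#' @return tibble (`treatment`, `linear_predictor`, `pred`).
#' @export
predict_depletion_fit <- function(fit) {
  w <- exp(apply(fit$draws[, seq_along(fit$cells), drop = FALSE], 2,
                 stats::median))
  acts <- tibble::as_tibble(as.data.frame.table(fit$activities,
                                                stringsAsFactors = FALSE))
  names(acts) <- c("treatment", "cell", "activity")
  predict_depletion(acts, stats::setNames(w, fit$cells))
}

#' Per-(treatment, cell type) depletion effects
#'
#' The contribution of each cell type to each treatment's predicted
#' depletion: the posterior distribution of \eqn{w_n x_n}, whose sum over
#' cell types is the linear predictor entering the exponential-CDF link.
#'
#' @param fit an `fcr_depletion_fit`.
#' @param probs interval probabilities for the uncertainty summary.
#' @return tibble (`treatment`, `cell`, `effect_median`, `effect_lo`,
#'   `effect_hi`).
#' @export
cell_type_effects <- function(fit, probs = c(0.25, 0.75)) {
  wi <- seq_along(fit$cells)
  w_draws <- exp(fit$draws[, wi, drop = FALSE])
  out <- tidyr::expand_grid(treatment = rownames(fit$activities),
                            cell = fit$cells)
  eff <- purrr::pmap(out, function(treatment, cell) {
    e <- w_draws[, cell == fit$cells] * fit$activities[treatment, cell]
    c(stats::median(e), stats::quantile(e, probs))
  })
  out$effect_median <- vapply(eff, `[`, 0, 1L)
  out$effect_lo <- vapply(eff, `[`, 0, 2L)
  out$effect_hi <- vapply(eff, `[`, 0, 3L)
  out
}
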