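#' Maximum a posteriori estimate for the binding-screen model
#'
#' Maximizes the model log posterior with L-BFGS on the log-scale free
#' parameter vector, starting from the prior modes (day scales start at
#' their conditional maximum-likelihood values). Deterministic: repeated
#' calls with the same inputs reproduce the estimate bit-identically.
#'
#' @param table measurement table; in the `"fit_affinity"` regime only
#'   pure-composition rows (`frac1` 0 or 1) enter the fit.
#' @param priors prior set from [build_priors()].
#' @param config a [fit_config()].
#' @return object of class `fcr_map`: free-parameter estimate (`par`), the
#'   log posterior value, convergence flag, and the parameter estimate in
#'   natural units via `tidy()`.
#' @export
map_estimate <- function(table, priors, config = fit_config()) {
  if (config$regime == "fixed_all") {
    rlang::abort("regime 'fixed_all' has no free parameters to optimize")
  }
  if (config$regime == "fit_affinity") {
    table <- dplyr::filter(table, .data$frac1 %in% c(0, 1))
  }
  ctx <- .build_context(table, priors, config$regime, l0 = config$l0)
  init <- .pack_init(ctx)
  neg <- function(x) -.log_posterior(x, ctx)
  opt <- stats::optim(init, neg, method = "L-BFGS-B",
                      control = list(maxit = config$map_maxit,
                                     ndeps = rep(1e-5, length(init)),
                                     factr = config$map_tol / .Machine$double.eps))
  if (opt$convergence != 0 && opt$convergence != 1) {
    rlang::warn(sprintf("MAP optimizer reported convergence code %d: %s",
                        opt$convergence, opt$message %||% ""))
  }
  par <- stats::setNames(opt$par, ctx$par_names)
  structure(list(par = par, value = -opt$value,
                 convergence = opt$convergence, ctx = ctx, config = config),
            class = "fcr_map")
}

#' @export
print.fcr_map <- function(x, ...) {
  cat("<fcr_map>", x$ctx$regime, "regime;", length(x$par),
      "free parameters; log posterior", sprintf("%.3f\n", x$value))
  invisible(x)
}

#' @rdname map_estimate
#' @param x an `fcr_map`.
#' @param ... unused.
#' @exportS3Method
tidy.fcr_map <- function(x, ...) {
  tibble::tibble(parameter = names(x$par), estimate = unname(x$par),
                 value = exp(unname(x$par)))
}

# Metropolis-Hastings with a mixture kernel: heavy-tailed (multivariate t)
# independence proposals centered on the MAP with the Laplace-approximation
# covariance, alternated with random-walk proposals whose global step size
# adapts toward 0.234 acceptance during warmup. When the Gaussian
# approximation is accurate the independence moves give near-independent
# draws; the random-walk component keeps the sampler exploring locally
# where it is not.
.amh <- function(lp_fun, init, cov0, warmup, draws, thin,
                 center = init, p_ind = 0.8, t_df = 10) {
  d <- length(init)
  ch <- chol(cov0 + diag(1e-10 * diag(cov0) + 1e-12, d))
  lam <- 2.38 / sqrt(d)
  m0 <- center
  logq <- function(y) {
    z <- backsolve(ch, y - m0, transpose = TRUE)
    -0.5 * (t_df + d) * log1p(sum(z^2) / t_df)
  }
  x <- init
  lp <- lp_fun(x)
  lq_x <- logq(x)
  keep <- matrix(NA_real_, draws, d)
  lp_keep <- numeric(draws)
  n_total <- warmup + draws * thin
  acc <- 0L
  for (it in seq_len(n_total)) {
    independent <- stats::runif(1) < p_ind
    if (independent) {
      z <- stats::rnorm(d) / sqrt(stats::rchisq(1, t_df) / t_df)
      prop <- m0 + drop(z %*% ch)
      lp_prop <- lp_fun(prop)
      lq_prop <- logq(prop)
      a <- min(1, exp(lp_prop - lp + lq_x - lq_prop))
    } else {
      prop <- x + lam * drop(stats::rnorm(d) %*% ch)
      lp_prop <- lp_fun(prop)
      a <- min(1, exp(lp_prop - lp))
    }
    if (is.finite(lp_prop) && stats::runif(1) < a) {
      x <- prop; lp <- lp_prop; acc <- acc + 1L
      lq_x <- if (independent) lq_prop else logq(x)
    }
    if (it <= warmup && !independent) {
      gam <- min(0.2, 5 / it^0.7)
      lam <- lam * exp(gam * (a - 0.234))
    }
    if (it > warmup) {
      k <- it - warmup
      if (k %% thin == 0) {
        keep[k %/% thin, ] <- x
        lp_keep[k %/% thin] <- lp
      }
    }
  }
  list(draws = keep, lp = lp_keep, accept = acc / n_total)
}

# split R-hat (two halves per chain)
.split_rhat <- function(draw_list) {
  halves <- list()
  for (dr in draw_list) {
    n <- nrow(dr)
    h <- n %/% 2
    halves <- c(halves, list(dr[seq_len(h), , drop = FALSE],
                             dr[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, stats::var))
  means <- matrix(means, ncol = m)
  vars <- matrix(vars, ncol = m)
  b <- n * apply(means, 1, stats::var)
  w <- rowMeans(vars)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Sample the binding-screen posterior
#'
#' Runs MCMC for the configured regime, initialized at the MAP estimate
#' with a Laplace-approximation proposal covariance. In the
#' `"fit_affinity"` regime only pure-composition (single-IgG) rows inform
#' the posterior; mixture conditions are held out for validation through
#' [posterior_predictive()].
#'
#' @inheritParams map_estimate
#' @param map optional precomputed [map_estimate()] (must match `config`).
#' @return object of class `fcr_posterior`: `draws` (retained draws x
#'   parameters), `chain` index per draw, per-parameter split R-hat,
#'   acceptance rates, the MAP, and the model context. `tidy()` gives
#'   per-parameter posterior medians and quartiles; `glance()` the
#'   diagnostics.
#' @export
sample_posterior <- function(table, priors, config = fit_config(),
                             map = NULL) {
  if (config$regime == "fixed_all") {
    rlang::abort("regime 'fixed_all' has no free parameters to sample")
  }
  if (is.null(map)) map <- map_estimate(table, priors, config)
  ctx <- map$ctx
  d <- length(map$par)
  lp_fun <- function(x) .log_posterior(x, ctx)

  # Laplace covariance at the MAP (finite-difference Hessian)
  hess <- stats::optimHess(unname(map$par), function(x) -lp_fun(x))
  ev <- eigen(hess, symmetric = TRUE)
  vals <- pmax(ev$values, max(abs(ev$values)) * 1e-8)
  cov0 <- ev$vectors %*% diag(1 / vals, d) %*% t(ev$vectors)

  chains <- vector("list", config$chains)
  accept <- numeric(config$chains)
  for (ci in seq_len(config$chains)) {
    set.seed(config$seed + ci - 1L)
    jitter <- drop(stats::rnorm(d) %*% chol(cov0 + diag(1e-12, d))) * 0.1
    res <- .amh(lp_fun, unname(map$par) + jitter, cov0,
                config$warmup, config$draws, config$thin,
                center = unname(map$par))
    chains[[ci]] <- res$draws
    accept[ci] <- res$accept
  }
  draws <- do.call(rbind, chains)
  colnames(draws) <- ctx$par_names
  rhat <- .split_rhat(chains)
  structure(list(
    draws = draws,
    chain = rep(seq_len(config$chains), each = config$draws),
    rhat = stats::setNames(rhat, ctx$par_names),
    accept = accept, map = map, ctx = ctx, config = config
  ), class = "fcr_posterior")
}

#' @export
print.fcr_posterior <- function(x, ...) {
  cat("<fcr_posterior>", x$ctx$regime, "regime;",
      nrow(x$draws), "draws x", ncol(x$draws), "parameters\n")
  cat(sprintf("  chains %d, acceptance %.2f, max split R-hat %.3f\n",
              x$config$chains, mean(x$accept), max(x$rhat)))
  invisible(x)
}

#' @rdname sample_posterior
#' @param x an `fcr_posterior`.
#' @param ... unused.
#' @exportS3Method
tidy.fcr_posterior <- function(x, ...) {
  q <- apply(x$draws, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  tibble::tibble(
    parameter = colnames(x$draws),
    median = q[2, ], q25 = q[1, ], q75 = q[3, ],
    rhat = unname(x$rhat[colnames(x$draws)])
  )
}

#' @rdname sample_posterior
#' @exportS3Method
glance.fcr_posterior <- function(x, ...) {
  tibble::tibble(
    regime = x$ctx$regime,
    chains = x$config$chains,
    draws = nrow(x$draws),
    parameters = ncol(x$draws),
    accept = mean(x$accept),
    max_rhat = max(x$rhat),
    lp_map = x$map$value
  )
}

#' Posterior summaries of the IgG-FcgR affinities, in natural units
#'
#' @param posterior an `fcr_posterior` from a `"fit_affinity"` run.
#' @return tibble: ligand, receptor, posterior median/quartiles of Ka (1/M)
#'   and of log10 Ka.
#' @export
affinity_estimates <- function(posterior) {
  nm <- colnames(posterior$draws)
  ka_cols <- grep("^logka\\[", nm)
  if (!length(ka_cols)) {
    rlang::abort("posterior has no affinity parameters (regime fit_affinity required)")
  }
  labels <- sub("^logka\\[(.+)\\]$", "\\1", nm[ka_cols])
  parts <- strsplit(labels, ",", fixed = TRUE)
  q <- apply(posterior$draws[, ka_cols, drop = FALSE], 2,
             stats::quantile, probs = c(0.25, 0.5, 0.75))
  tibble::tibble(
    ligand = vapply(parts, `[`, "", 1L),
    receptor = vapply(parts, `[`, "", 2L),
    ka_median = exp(q[2, ]), ka_q25 = exp(q[1, ]), ka_q75 = exp(q[3, ]),
    log10_ka_median = q[2, ] / log(10)
  )
}

#' Posterior predictive distribution of binding conditions
#'
#' Pushes posterior draws through the forward binding model for a set of
#' conditions and summarises the predictive distribution of normalized RFU.
#' Mixture conditions are predicted from the same per-draw parameters as the
#' pure conditions the posterior was trained on, so posteriors trained on
#' single-IgG rows alone yield genuine out-of-mixture predictions.
#'
#' @param samples an `fcr_posterior`.
#' @param conditions tibble with columns `receptor`, `valency`, `pair`,
#'   `frac1`, and optionally `day` (when absent, the across-day mean log
#'   scale factor is used).
#' @param max_draws cap on the number of posterior draws pushed through the
#'   model (subsampled deterministically).
#' @return `conditions` with predictive `pred_median`, `pred_q25`,
#'   `pred_q75` columns appended.
#' @export
posterior_predictive <- function(samples, conditions, max_draws = 200L) {
  ctx <- samples$ctx
  pm <- .split_pair(conditions$pair)
  unk <- c(setdiff(unique(c(pm$first, pm$second)), ctx$ligands),
           setdiff(unique(conditions$receptor), ctx$receptors))
  if (length(unk)) {
    rlang::abort(paste0("unknown ligand/receptor label(s): ",
                        paste(unk, collapse = ", ")))
  }
  lig1 <- match(pm$first, ctx$ligands)
  lig2 <- match(pm$second, ctx$ligands)
  recep <- match(conditions$receptor, ctx$receptors)
  vi <- match(conditions$valency, ctx$valencies)
  if (anyNA(vi)) rlang::abort("condition valency absent from the fitted model")
  day_idx <- if ("day" %in% names(conditions)) match(conditions$day, ctx$days)
             else rep(NA_integer_, nrow(conditions))

  n <- nrow(samples$draws)
  pick <- unique(round(seq(1, n, length.out = min(max_draws, n))))
  preds <- matrix(NA_real_, nrow(conditions), length(pick))
  for (k in seq_along(pick)) {
    th <- .unpack(samples$draws[pick[k], ], ctx)
    ka <- exp(th$logka)
    ka_eff <- conditions$frac1 * ka[cbind(lig1, recep)] +
      (1 - conditions$frac1) * ka[cbind(lig2, recep)]
    rtot <- exp(th$logrtot)[recep]
    f <- exp(th$logf)[vi]
    kx <- exp(th$logkx)
    s <- .solve_s_vec(ka_eff, rtot, ctx$l0, f, kx)
    lsc <- ifelse(is.na(day_idx), mean(th$logscale), th$logscale[day_idx])
    if (!length(th$logscale)) lsc <- 0
    preds[, k] <- exp(log(ctx$l0 / kx) + log(s^f - 1) + lsc)
  }
  q <- apply(preds, 1, stats::quantile, probs = c(0.25, 0.5, 0.75))
  dplyr::mutate(tibble::as_tibble(conditions),
                pred_median = q[2, ], pred_q25 = q[1, ], pred_q75 = q[3, ])
}

#' Validate a fixed affinity set against a binding dataset
#'
#' Pins the Fc-FcgR affinities to a supplied set (documented or updated)
#' and lets MCMC fit every other parameter (receptor abundances, effective
#' valencies, crosslinking constant, day scales, noise), then scores the
#' concordance between measured and predicted binding. Used to compare
#' affinity sets on an independent dataset.
#'
#' @param table measurement table of the validation dataset.
#' @param affinity_set tidy table (`ligand`, `receptor`, `ka`) of the
#'   affinities to hold fixed.
#' @param priors prior set built for the validation dataset (its expression
#'   replicates and valencies).
#' @param config a [fit_config()]; the regime is forced to
#'   `"fit_nonaffinity"`.
#' @return object of class `fcr_validation`: the posterior, a predictions
#'   tibble, and `concordance` (Pearson correlation of log predictions vs
#'   log measurements at the posterior median parameters).
#' @export
validate_with_fixed_affinities <- function(table, affinity_set, priors,
                                           config = fit_config()) {
  config$regime <- "fit_nonaffinity"
  ctx <- .build_context(table, priors, "fit_nonaffinity", l0 = config$l0,
                        fixed_affinities = affinity_set)
  init <- .pack_init(ctx)
  neg <- function(x) -.log_posterior(x, ctx)
  opt <- stats::optim(init, neg, method = "L-BFGS-B",
                      control = list(maxit = config$map_maxit))
  map <- structure(list(par = stats::setNames(opt$par, ctx$par_names),
                        value = -opt$value, convergence = opt$convergence,
                        ctx = ctx, config = config), class = "fcr_map")
  post <- sample_posterior(table, priors, config, map = map)
  med <- apply(post$draws, 2, stats::median)
  th <- .unpack(med, ctx)
  lpred <- .predict_log_lbound(th, ctx) + th$logscale[ctx$rows$day]
  structure(list(
    posterior = post,
    predictions = dplyr::mutate(tibble::as_tibble(table),
                                pred = exp(lpred)),
    concordance = stats::cor(ctx$rows$log_rfu, lpred)
  ), class = "fcr_validation")
}

#' @export
print.fcr_validation <- function(x, ...) {
  cat("<fcr_validation> concordance (log-scale Pearson r):",
      sprintf("%.3f\n", x$concordance))
  invisible(x)
}
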