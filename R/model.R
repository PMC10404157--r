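#' Fitting configuration for the binding-screen posterior
#'
#' @param regime one of `"fit_affinity"` (affinities and all nuisance
#'   parameters free; only pure-composition rows enter the likelihood, the
#'   mixtures being reserved for validation), `"fit_nonaffinity"` (affinities
#'   pinned to their prior modes, everything else free), or `"fixed_all"`
#'   (no free parameters; deterministic predictive residual scoring).
#' @param chains,draws,warmup,thin MCMC settings: `draws` retained samples
#'   per chain after `warmup` adaptation iterations, keeping every
#'   `thin`-th iteration.
#' @param seed integer seed governing every stochastic step.
#' @param l0 immune-complex concentration (M) used in the forward model.
#' @param map_maxit iteration cap for the MAP optimizer.
#' @param map_tol relative tolerance for the MAP optimizer.
#' @return a `fit_config` list.
#' @export
fit_config <- function(regime = c("fit_affinity", "fit_nonaffinity", "fixed_all"),
                       chains = 2L, draws = 500L, warmup = 500L, thin = 5L,
                       seed = 1L, l0 = 1e-9, map_maxit = 500L,
                       map_tol = 1e-10) {
  regime <- match.arg(regime)
  stopifnot(chains >= 1, draws >= 1, warmup >= 1, thin >= 1)
  structure(list(regime = regime, chains = as.integer(chains),
                 draws = as.integer(draws), warmup = as.integer(warmup),
                 thin = as.integer(thin), seed = as.integer(seed), l0 = l0,
                 map_maxit = as.integer(map_maxit), map_tol = map_tol),
            class = "fit_config")
}

# Internal model context: indexes the measurement table against the prior
# set and lays out the free-parameter vector for a given regime.
#
# Parameter blocks (all on natural-log scale):
#   logka     [n_ligand x n_receptor]   free iff regime == "fit_affinity"
#   logrtot   [n_receptor]              free unless fixed_all
#   logf      [one per valency]         free unless fixed_all
#   logkx                               free unless fixed_all
#   logscale  [one per day]             free unless fixed_all (ML-profiled
#                                       in fixed_all)
#   logsigma                            free unless fixed_all
.build_context <- function(table, priors, regime, l0 = 1e-9,
                           fixed_affinities = NULL) {
  ligands <- sort(unique(priors$affinity$ligand))
  receptors <- sort(unique(priors$expression$receptor))
  if (nrow(table) > 0) {
    pm <- .split_pair(table$pair)
    unk_l <- setdiff(unique(c(pm$first, pm$second)), ligands)
    unk_r <- setdiff(unique(table$receptor), receptors)
    if (length(unk_l)) rlang::abort(paste0("unknown ligand(s): ",
                                           paste(unk_l, collapse = ", ")))
    if (length(unk_r)) rlang::abort(paste0("unknown receptor label(s): ",
                                           paste(unk_r, collapse = ", ")))
  }
  days <- if (nrow(table) > 0) sort(unique(table$day)) else character(0)
  valencies <- sort(unique(c(priors$valency$valency,
                             if (nrow(table) > 0) table$valency)))

  ka_prior <- priors$affinity
  mu_ka <- matrix(NA_real_, length(ligands), length(receptors),
                  dimnames = list(ligands, receptors))
  sd_ka <- mu_ka
  idx <- cbind(match(ka_prior$ligand, ligands),
               match(ka_prior$receptor, receptors))
  mu_ka[idx] <- ka_prior$mu
  sd_ka[idx] <- ka_prior$sigma
  mode_ka <- mu_ka
  mode_ka[idx] <- log(ka_prior$mode)
  if (anyNA(mu_ka)) rlang::abort("affinity priors incomplete over ligand x receptor")

  em <- priors$expression[match(receptors, priors$expression$receptor), ]
  vs <- priors$valency$sigma[match(valencies, priors$valency$valency)]
  vs[is.na(vs)] <- 0.2

  ctx <- list(
    ligands = ligands, receptors = receptors, days = days,
    valencies = valencies, regime = regime, l0 = l0,
    mu = list(logka = mu_ka, logrtot = em$mu, logf = log(valencies),
              logkx = unname(priors$kx_star[["mu"]]),
              logscale = rep(priors$scale[["mu"]], length(days)),
              logsigma = unname(priors$noise[["mu"]])),
    sd = list(logka = sd_ka, logrtot = em$sigma, logf = vs,
              logkx = unname(priors$kx_star[["sigma"]]),
              logscale = rep(priors$scale[["sigma"]], length(days)),
              logsigma = unname(priors$noise[["sigma"]])),
    mode_ka = mode_ka
  )

  if (!is.null(fixed_affinities)) {
    fa <- matrix(NA_real_, length(ligands), length(receptors),
                 dimnames = list(ligands, receptors))
    fa[cbind(match(fixed_affinities$ligand, ligands),
             match(fixed_affinities$receptor, receptors))] <-
      log(pmax(fixed_affinities$ka, 1)) # guard log(0) for non-binders
    if (anyNA(fa)) rlang::abort("fixed affinity set incomplete")
    ctx$mode_ka <- fa
  }

  if (nrow(table) > 0) {
    # technical replicates share the model prediction: solve each unique
    # condition once per likelihood evaluation
    key <- ifelse(
      table$frac1 == 1, paste("pure", pm$first),
      ifelse(table$frac1 == 0, paste("pure", pm$second),
             paste(pm$first, pm$second, table$frac1)))
    key <- paste(key, table$receptor, table$valency)
    uniq <- !duplicated(key)
    cond <- match(key, key[uniq])
    ctx$rows <- list(
      log_rfu = log(table$rfu),
      day = match(table$day, days),
      cond = cond,
      frac1 = table$frac1[uniq],
      lig1 = match(pm$first[uniq], ligands),
      lig2 = match(pm$second[uniq], ligands),
      recep = match(table$receptor[uniq], receptors),
      val = match(table$valency[uniq], valencies)
    )
  } else {
    ctx$rows <- NULL
  }

  free <- switch(regime,
    fit_affinity = c("logka", "logrtot", "logf", "logkx", "logscale",
                     "logsigma"),
    fit_nonaffinity = c("logrtot", "logf", "logkx", "logscale", "logsigma"),
    fixed_all = character(0)
  )
  ctx$free_blocks <- free
  ctx$par_names <- .par_names(ctx)
  ctx
}

.par_names <- function(ctx) {
  out <- character(0)
  for (b in ctx$free_blocks) {
    out <- c(out, switch(b,
      logka = paste0("logka[", rep(ctx$ligands, times = length(ctx$receptors)),
                     ",", rep(ctx$receptors, each = length(ctx$ligands)), "]"),
      logrtot = paste0("logrtot[", ctx$receptors, "]"),
      logf = paste0("logf[", ctx$valencies, "]"),
      logkx = "logkx",
      logscale = if (length(ctx$days)) paste0("logscale[", ctx$days, "]")
                 else character(0),
      logsigma = "logsigma"
    ))
  }
  out
}

# theta: full parameter list at the regime's fixed values + free vector x
.unpack <- function(x, ctx) {
  th <- list(logka = ctx$mode_ka, logrtot = ctx$mu$logrtot,
             logf = ctx$mu$logf, logkx = ctx$mu$logkx,
             logscale = ctx$mu$logscale, logsigma = ctx$mu$logsigma)
  pos <- 0L
  for (b in ctx$free_blocks) {
    n <- length(th[[b]])
    th[[b]][] <- x[pos + seq_len(n)]
    pos <- pos + n
  }
  th
}

.pack_init <- function(ctx) {
  th <- list(logka = ctx$mode_ka, logrtot = ctx$mu$logrtot,
             logf = ctx$mu$logf, logkx = ctx$mu$logkx,
             logscale = ctx$mu$logscale, logsigma = ctx$mu$logsigma)
  # start the day scales at their conditional ML value given the other inits
  if (!is.null(ctx$rows) && "logscale" %in% ctx$free_blocks) {
    lpred <- .predict_log_lbound(th, ctx)
    resid <- ctx$rows$log_rfu - lpred
    ml <- tapply(resid, ctx$rows$day, mean)
    th$logscale[as.integer(names(ml))] <- as.numeric(ml)
  }
  unlist(lapply(ctx$free_blocks, function(b) as.numeric(th[[b]])))
}

# log Lbound per table row; each CHO line expresses a single receptor, so
# the mixture collapses to a composition-weighted scalar affinity and the
# equilibrium is solved for all unique conditions at once, then expanded to
# replicate rows.
.predict_log_lbound <- function(th, ctx) {
  r <- ctx$rows
  ka <- exp(th$logka)
  ka_eff <- r$frac1 * ka[cbind(r$lig1, r$recep)] +
    (1 - r$frac1) * ka[cbind(r$lig2, r$recep)]
  rtot <- exp(th$logrtot)[r$recep]
  f <- exp(th$logf)[r$val]
  kx <- exp(th$logkx)
  s <- .solve_s_vec(ka_eff, rtot, ctx$l0, f, kx)
  (log(ctx$l0 / kx) + log(s^f - 1))[r$cond]
}

.log_prior <- function(th, ctx) {
  lp <- 0
  for (b in ctx$free_blocks) {
    lp <- lp + sum(stats::dnorm(as.numeric(th[[b]]),
                                as.numeric(ctx$mu[[b]]),
                                as.numeric(ctx$sd[[b]]), log = TRUE))
  }
  lp
}

.log_lik <- function(th, ctx) {
  if (is.null(ctx$rows)) return(0)
  lpred <- .predict_log_lbound(th, ctx)
  mu <- lpred + th$logscale[ctx$rows$day]
  sigma <- exp(th$logsigma)
  if (!all(is.finite(mu))) return(-Inf)
  sum(stats::dnorm(ctx$rows$log_rfu, mu, sigma, log = TRUE))
}

.log_posterior <- function(x, ctx) {
  th <- .unpack(x, ctx)
  lp <- .log_prior(th, ctx)
  if (!is.finite(lp)) return(-Inf)
  ll <- .log_lik(th, ctx)
  if (!is.finite(ll)) return(-Inf)
  lp + ll
}

#' Log posterior of the binding-screen model
#'
#' Evaluates log prior + log likelihood of the measured RFU under the
#' multivalent binding model: predicted bound-complex amounts per row are
#' scaled by a per-day factor linking model units to normalized RFU, with
#' multiplicative (log-normal) measurement noise shared across rows. In the
#' `"fixed_all"` regime there are no free parameters; the value returned is
#' the deterministic residual score obtained by profiling out the per-day
#' scales and noise scale at their conditional maximum-likelihood values.
#'
#' @param params named list of parameter values in natural units:
#'   `ka` (tidy table or NL x NR matrix), `rtot` (named by receptor), `f`
#'   (named by valency), `kx_star`, `scale` (named by day), `sigma`. Any
#'   missing element falls back to the regime's fixed value (prior mode).
#' @param table measurement table (see [read_measurements()]).
#' @param priors prior set from [build_priors()].
#' @param regime fitting regime, see [fit_config()].
#' @param l0 complex concentration (M).
#' @return scalar log posterior.
#' @export
model_log_posterior <- function(params, table, priors,
                                regime = "fit_affinity", l0 = 1e-9) {
  if (regime == "fit_affinity") {
    table <- dplyr::filter(table, .data$frac1 %in% c(0, 1))
  }
  ctx <- .build_context(table, priors, regime, l0 = l0)
  th <- .theta_from_params(params, ctx)
  if (ctx$regime == "fixed_all") {
    return(.residual_score(th, ctx))
  }
  .log_prior(th, ctx) + .log_lik(th, ctx)
}

.theta_from_params <- function(params, ctx) {
  th <- list(logka = ctx$mode_ka, logrtot = ctx$mu$logrtot,
             logf = ctx$mu$logf, logkx = ctx$mu$logkx,
             logscale = ctx$mu$logscale, logsigma = ctx$mu$logsigma)
  if (!is.null(params$ka)) {
    ka <- if (is.matrix(params$ka)) params$ka else affinity_matrix(params$ka)
    th$logka <- log(ka[ctx$ligands, ctx$receptors, drop = FALSE])
  }
  if (!is.null(params$rtot)) th$logrtot <- log(params$rtot[ctx$receptors])
  if (!is.null(params$f)) {
    th$logf <- log(params$f[as.character(ctx$valencies)])
  }
  if (!is.null(params$kx_star)) th$logkx <- log(params$kx_star)
  if (!is.null(params$scale)) th$logscale <- log(params$scale[ctx$days])
  if (!is.null(params$sigma)) th$logsigma <- log(params$sigma)
  th
}

# fixed_all: per-day scale and noise profiled at their conditional ML;
# returns the resulting log likelihood (a deterministic residual score)
.residual_score <- function(th, ctx) {
  if (is.null(ctx$rows)) return(0)
  lpred <- .predict_log_lbound(th, ctx)
  resid <- ctx$rows$log_rfu - lpred
  ml_scale <- tapply(resid, ctx$rows$day, mean)
  centred <- resid - as.numeric(ml_scale)[ctx$rows$day]
  sigma <- sqrt(mean(centred^2))
  sum(stats::dnorm(centred, 0, sigma, log = TRUE))
}
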