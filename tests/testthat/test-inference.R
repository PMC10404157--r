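test_that("MAP is deterministic and self-consistent on near-noiseless data", {
  # generate data from parameters at the prior's stationary point (prior
  # log-mean for each affinity, nominal valencies and crosslinking
  # constant): those parameters must maximize the posterior, so the MAP
  # recovers them from near-noiseless data
  priors <- build_priors(small_affinities(),
                         simulate_expression_replicates(
                           small_truth(21), cv = 0.001, seed = 21))
  truth <- small_truth(seed = 21, noise_cv = 0.001)
  truth$affinity <- dplyr::transmute(priors$affinity, ligand, receptor,
                                     ka = exp(mu))
  truth$expression <- stats::setNames(exp(priors$expression$mu),
                                      priors$expression$receptor)
  design <- generate_design(receptors = small_receptors)
  screen <- simulate_binding_screen(truth, design, seed = 21,
                                    noise_cv = 0.001)
  cfg_fast <- quick_config(seed = 5)
  cfg_fast$map_maxit <- 100L
  expect_identical(map_estimate(screen, priors, cfg_fast)$par,
                   map_estimate(screen, priors, cfg_fast)$par)

  cfg <- quick_config(seed = 5)
  cfg$map_maxit <- 2000L
  map1 <- map_estimate(screen, priors, cfg)

  # the identifiable content -- the per-condition binding predictions, up
  # to the per-day scale -- is recovered to well under 1%; individual
  # affinities carry a residual few-percent spread along the soft
  # scale/valency/crosslinking ridge the priors resolve
  ctx <- map1$ctx
  th_map <- fcbindr:::.unpack(unname(map1$par), ctx)
  th_true <- fcbindr:::.theta_from_params(
    list(ka = truth$affinity, rtot = truth$expression, f = truth$f,
         kx_star = truth$kx_star), ctx)
  dd <- fcbindr:::.predict_log_lbound(th_map, ctx) -
    fcbindr:::.predict_log_lbound(th_true, ctx)
  centred <- dd - stats::ave(dd, ctx$rows$day)
  expect_lt(max(abs(centred)), 0.01)

  tm <- stats::setNames(log(truth$affinity$ka),
                        paste0("logka[", truth$affinity$ligand, ",",
                               truth$affinity$receptor, "]"))
  expect_lt(max(abs(map1$par[names(tm)] - tm)), 0.05)
})

test_that("fit_nonaffinity holds affinities at their documented modes", {
  screen <- small_screen(seed = 22)
  priors <- small_priors()
  map <- map_estimate(screen, priors, quick_config("fit_nonaffinity"))
  expect_false(any(grepl("^logka", names(map$par))))
  expect_true(any(grepl("^logrtot", names(map$par))))
  post <- sample_posterior(screen, priors, quick_config("fit_nonaffinity"),
                           map = map)
  expect_false(any(grepl("^logka", colnames(post$draws))))
  expect_error(map_estimate(screen, priors, quick_config("fixed_all")),
               "no free parameters")
})

test_that("posterior sampling is reproducible and mixes on the small screen", {
  screen <- small_screen(seed = 23)
  priors <- small_priors()
  cfg <- quick_config(seed = 7)
  post1 <- sample_posterior(screen, priors, cfg)
  post2 <- sample_posterior(screen, priors, cfg)
  expect_identical(post1$draws, post2$draws) # same seed, same draws
  expect_lt(max(post1$rhat), 1.1)
  expect_equal(nrow(post1$draws), cfg$chains * cfg$draws)
  expect_true(all(is.finite(post1$draws)))
  td <- tidy(post1)
  expect_true(all(c("parameter", "median", "q25", "q75", "rhat") %in%
                    names(td)))
})

test_that("prior-only sampling reproduces the prior quantiles", {
  priors <- small_priors()
  empty <- tibble::tibble(day = character(), receptor = character(),
                          valency = numeric(), pair = character(),
                          frac1 = numeric(), replicate = integer(),
                          rfu = numeric())
  post <- sample_posterior(empty, priors,
                           fit_config(regime = "fit_affinity", chains = 2,
                                      draws = 400, warmup = 200, thin = 2,
                                      seed = 2))
  kx <- post$draws[, "logkx"]
  expect_lt(abs(stats::median(kx) - log(6.31e-13)), 0.4) # prior sd = 2
  expect_lt(abs(stats::quantile(kx, 0.75) - stats::quantile(kx, 0.25) -
                  2 * stats::qnorm(0.75) * 2), 0.6)
  f4 <- post$draws[, "logf[4]"]
  expect_lt(abs(stats::median(f4) - log(4)), 0.05)
})

test_that("posteriors trained on pure rows predict held-out mixtures", {
  truth <- small_truth(seed = 31)
  design <- generate_design(receptors = small_receptors)
  screen <- simulate_binding_screen(truth, design, seed = 31)
  priors <- build_priors(small_affinities(),
                         simulate_expression_replicates(truth, seed = 31))
  post <- sample_posterior(screen, priors, quick_config(seed = 3))

  mix <- dplyr::distinct(dplyr::filter(screen, !frac1 %in% c(0, 1)),
                         day, receptor, valency, pair, frac1)
  pp <- posterior_predictive(post, mix)
  truth_l <- fcbindr:::.design_lbound(truth, mix)
  st <- spearman_test(pp$pred_median, truth_l)
  expect_gte(st$rho, 0.9)

  # endpoint identity: the two pure endpoints reproduce the pure
  # single-ligand predictions no matter which pair expresses them
  ends <- tibble::tibble(
    receptor = "FcgRI", valency = 4,
    pair = c("IgG1/IgG2", "IgG1/IgG3", "IgG2/IgG1"),
    frac1 = c(1, 1, 0))
  pe <- posterior_predictive(post, ends)
  expect_equal(pe$pred_median[1], pe$pred_median[2], tolerance = 1e-12)
  expect_equal(pe$pred_median[1], pe$pred_median[3], tolerance = 1e-12)
  expect_error(posterior_predictive(post, dplyr::mutate(ends, receptor = "Rx")),
               "unknown")
})

test_that("validation with fixed affinities favors the generating set", {
  truth <- small_truth(seed = 41)
  # validation-style dataset: single subclasses at valencies 4 and 26
  truth$f <- stats::setNames(c(4, 26), c(4, 26))
  truth$batch_scale <- truth$batch_scale[1:2]
  design <- generate_design(receptors = small_receptors,
                            subclasses = c("IgG1", "IgG2"),
                            valencies = c(4, 26), fractions = c(1, 0))
  screen <- simulate_binding_screen(truth, design, seed = 41)
  priors <- build_priors(small_affinities(),
                         simulate_expression_replicates(truth, seed = 41),
                         valencies = c(4, 26))
  cfg <- quick_config(seed = 9)
  v_true <- validate_with_fixed_affinities(screen, truth$affinity, priors,
                                           cfg)
  expect_true("logf[26]" %in% colnames(v_true$posterior$draws))
  perturbed <- dplyr::mutate(
    truth$affinity,
    ka = ka * ifelse(ligand == "IgG1" & receptor == "FcgRI", 10, 1))
  v_pert <- validate_with_fixed_affinities(screen, perturbed, priors, cfg)
  expect_gt(v_true$concordance, v_pert$concordance)
  # determinism under identical inputs
  v_again <- validate_with_fixed_affinities(screen, truth$affinity, priors,
                                            cfg)
  expect_identical(v_true$posterior$draws, v_again$posterior$draws)
})

test_that("high-valency screens constrain low-affinity interactions better", {
  truth <- small_truth(seed = 51)
  design <- generate_design(receptors = small_receptors,
                            subclasses = c("IgG1", "IgG2"))
  screen <- simulate_binding_screen(truth, design, seed = 51)
  priors <- build_priors(small_affinities(),
                         simulate_expression_replicates(truth, seed = 51))
  iqr_of <- function(valency) {
    sub <- dplyr::filter(screen, valency == !!valency)
    post <- sample_posterior(sub, priors, quick_config(seed = 4))
    draws <- post$draws[, "logka[IgG2,FcgRI]"] # truth at the 1e4 clip
    unname(diff(stats::quantile(draws, c(0.25, 0.75))))
  }
  expect_lt(iqr_of(33), iqr_of(4))
})
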