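test_that("the factorial design enumerates the full screen", {
  d <- generate_design()
  expect_equal(nrow(d), 6 * 2 * 6 * 6)
  expect_equal(dplyr::n_distinct(d$receptor), 6)
  expect_equal(dplyr::n_distinct(d$pair), 6)
  expect_setequal(unique(d$valency), c(4, 33))
  expect_equal(sort(unique(d$frac1)), sort(composition_series))
  # both pure endpoints present for every pair
  ends <- d |>
    dplyr::filter(frac1 %in% c(0, 1)) |>
    dplyr::count(pair, valency, receptor)
  expect_true(all(ends$n == 2))
})

test_that("simulated screens carry their ground truth and normalize per day", {
  truth <- binding_ground_truth(seed = 5)
  screen <- simulate_binding_screen(truth, seed = 5)
  expect_equal(nrow(screen), 432 * 3)
  gt <- attr(screen, "ground_truth")
  expect_equal(gt$seed, 5)
  gm <- tapply(log(screen$rfu), screen$day, mean)
  expect_true(all(abs(gm) < 1e-9))
  # bit-identical regeneration under the same seed
  screen2 <- simulate_binding_screen(truth, seed = 5)
  expect_identical(screen$rfu, screen2$rfu)
  # different seed gives different data
  expect_false(identical(
    screen$rfu, simulate_binding_screen(truth, seed = 6)$rfu))
})

test_that("zero technical noise returns exact scaled model predictions", {
  truth <- small_truth(seed = 8, noise_cv = 0)
  design <- generate_design(receptors = small_receptors,
                            subclasses = c("IgG1", "IgG2"))
  screen <- simulate_binding_screen(truth, design, seed = 8, noise_cv = 0)
  pred <- fcbindr:::.design_lbound(truth, screen)
  gm <- tapply(log(pred), screen$day, mean)
  expect_equal(screen$rfu, pred / exp(gm[screen$day]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("simulated noise matches the requested coefficient of variation", {
  truth <- small_truth(seed = 13, noise_cv = 0.2)
  design <- generate_design(receptors = "FcgRI",
                            subclasses = c("IgG1", "IgG2"),
                            valencies = 4, fractions = 1)
  screen <- simulate_binding_screen(truth, design, replicates = 10000,
                                    seed = 13)
  sigma <- sqrt(log(1 + 0.2^2))
  expect_lt(abs(stats::sd(log(screen$rfu)) - sigma) / sigma, 0.05)
})

test_that("expression replicates recover their generating distribution", {
  truth <- small_truth(seed = 17)
  reps <- simulate_expression_replicates(truth, n = 200, cv = 0.15,
                                         seed = 17)
  gm <- reps |>
    dplyr::group_by(receptor) |>
    dplyr::summarise(g = exp(mean(log(rtot))), s = stats::sd(log(rtot)),
                     .groups = "drop")
  expect_equal(gm$g, unname(truth$expression[gm$receptor]),
               tolerance = 0.05)
  sigma <- sqrt(log(1 + 0.15^2))
  expect_true(all(abs(gm$s - sigma) / sigma < 0.2))
  expect_identical(reps,
                   simulate_expression_replicates(truth, n = 200, cv = 0.15,
                                                  seed = 17))
  expect_error(simulate_expression_replicates(truth, n = 1), ">= 2")
})

test_that("forward simulations show the screen's qualitative signatures", {
  truth <- binding_ground_truth(seed = 19, noise_cv = 0)
  screen <- simulate_binding_screen(truth, seed = 19, noise_cv = 0)
  pure <- screen |>
    dplyr::filter(frac1 %in% c(0, 1)) |>
    dplyr::mutate(subclass = {
      pm <- fcbindr:::.split_pair(pair)
      ifelse(frac1 == 1, pm$first, pm$second)
    }) |>
    dplyr::group_by(receptor, subclass, valency) |>
    dplyr::summarise(m = stats::median(rfu), .groups = "drop") |>
    dplyr::left_join(truth$affinity,
                     by = c("receptor", "subclass" = "ligand"))
  # binding increases with documented affinity
  st <- spearman_test(log(pure$m), log(pure$ka))
  expect_gt(st$rho, 0.5)
  expect_lt(st$p_value, 1e-6)
  # valency 33 engages at least as much receptor as valency 4 everywhere;
  # bound-complex counts can invert under receptor limitation because each
  # high-valency complex occupies many receptors, so the avidity claim is
  # asserted on the receptor-bound amount
  cond <- dplyr::distinct(screen, receptor, pair, frac1, valency)
  rb <- vapply(seq_len(nrow(cond)), function(i) {
    pm <- fcbindr:::.split_pair(cond$pair[i])
    ka <- affinity_matrix(truth$affinity)
    eq <- solve_equilibrium(
      receptor_pool(cond$receptor[i],
                    truth$expression[cond$receptor[i]]),
      complex_mixture(1e-9, truth$f[as.character(cond$valency[i])],
                      1, truth$kx_star),
      matrix(cond$frac1[i] * ka[pm$first, cond$receptor[i]] +
               (1 - cond$frac1[i]) * ka[pm$second, cond$receptor[i]],
             1, 1))
    eq$receptors$rbound
  }, 0)
  wide <- dplyr::mutate(cond, rb = rb) |>
    tidyr::pivot_wider(names_from = valency, values_from = rb,
                       names_prefix = "v")
  expect_true(all(wide$v33 >= wide$v4))
})

test_that("depletion studies concentrate around the linked predictions", {
  profiles <- effector_cell_profiles()
  # zero weights: depletion near zero
  d0 <- simulate_depletion_study(truth_weights = c(cMO = 0, ncMO = 0,
                                                   Neu = 0),
                                 profiles = profiles, seed = 2)
  expect_lt(max(d0$y), 0.05)
  # tight concentration limit: per-treatment means approach the prediction
  dn <- simulate_depletion_study(n_mice = 200, concentration = 5000,
                                 seed = 2)
  gt <- attr(dn, "ground_truth")
  means <- tapply(dn$y, dn$treatment, mean)
  expect_equal(as.numeric(means[gt$predictions$treatment]),
               gt$predictions$pred, tolerance = 0.02)
  expect_identical(simulate_depletion_study(seed = 9)$y,
                   simulate_depletion_study(seed = 9)$y)
})

test_that("ground-truth manifests serialize with their seed", {
  truth <- small_truth(seed = 33)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  m <- jsonlite::read_json(path)
  expect_equal(m$seed, 33)
  expect_equal(m$kx_star, 6.31e-13)
  expect_equal(length(m$batch_scale), 3)
  expect_equal(m$affinity[[1]]$ligand, "IgG1")
})
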