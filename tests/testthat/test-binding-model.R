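test_that("phi matrix follows its defining formula and simplex structure", {
  # zero affinity: only the unbound slot carries weight
  phi0 <- compute_phi(c(1e5, 2e5), matrix(0, 2, 2), 1e-12, c(0.3, 0.7))
  expect_equal(unname(phi0[, 1]), c(0.3, 0.7))
  expect_true(all(phi0[, -1] == 0))

  # direct arithmetic: phi_11 = req * ka * kx * C
  phi <- compute_phi(1e5, matrix(1e6, 1, 1), 1e-12, 1)
  expect_equal(unname(phi[1, 2]), 0.1)
  expect_equal(unname(phi[1, 1]), 1)

  # unbound column always sums to 1 for any simplex composition
  set.seed(1)
  for (i in 1:20) {
    nl <- sample(1:3, 1); nr <- sample(1:3, 1)
    comp <- stats::runif(nl); comp <- comp / sum(comp)
    phi <- compute_phi(stats::runif(nr, 1, 1e5),
                       matrix(10^stats::runif(nl * nr, 3, 7), nl, nr),
                       1e-12, comp)
    expect_equal(sum(phi[, 1]), 1)
  }

  expect_error(compute_phi(1, matrix(1, 2, 2), 1e-12, c(0.5, 0.5)),
               "dimension")
  expect_error(compute_phi(c(-1, 1), matrix(1, 2, 2), 1e-12, c(0.5, 0.5)),
               "nonnegative")
})

test_that("closed-form macroscopic quantities have the right limits", {
  phi0 <- compute_phi(c(1e5), matrix(0, 1, 1), 1e-12, 1)
  expect_equal(lbound_closed_form(phi0, 1e-9, 4, 1e-12), 0)

  # monovalent single-ligand limit is Langmuir: lbound = l0 * ka * req
  req <- 3e4; ka <- 2e6; kx <- 5e-13; l0 <- 1e-9
  phi <- compute_phi(req, matrix(ka, 1, 1), kx, 1)
  expect_equal(lbound_closed_form(phi, l0, 1, kx), l0 * ka * req,
               tolerance = 1e-12)

  # receptor with zero affinity column binds nothing
  ka2 <- matrix(c(1e6, 0), 1, 2)
  phi2 <- compute_phi(c(1e5, 1e5), ka2, kx, 1)
  expect_equal(unname(rbound_closed_form(phi2, l0, 2, kx, n = 2)), 0)

  # at f = 1 summed bound receptor equals bound complexes, and no
  # crosslinking is possible
  phi3 <- compute_phi(c(2e4, 7e4), matrix(c(1e6, 3e5, 2e5, 9e5), 2, 2),
                      kx, c(0.4, 0.6))
  expect_equal(sum(rbound_closed_form(phi3, l0, 1, kx)),
               lbound_closed_form(phi3, l0, 1, kx), tolerance = 1e-12)
  expect_equal(unname(rmulti_closed_form(phi3, l0, 1, kx)), c(0, 0))

  expect_error(lbound_closed_form(phi3, l0, 2, 0), "kx_star")
  expect_error(rbound_closed_form(phi3, l0, 2, kx, n = 5), "index")
})

test_that("closed forms match the configuration-enumeration oracle", {
  set.seed(20)
  for (f in 1:4) {
    for (nl in 1:3) {
      for (nr in 1:3) {
        for (rep in 1:8) {
          comp <- stats::runif(nl); comp <- comp / sum(comp)
          phi <- compute_phi(10^stats::runif(nr, 2, 5),
                             matrix(10^stats::runif(nl * nr, 3, 7), nl, nr),
                             10^stats::runif(1, -13, -11), comp)
          l0 <- 10^stats::runif(1, -10, -8)
          kx <- 10^stats::runif(1, -13, -11)
          o <- oracle_sums(phi, l0, f, kx)
          expect_lt(rel_err(o$lbound,
                            lbound_closed_form(phi, l0, f, kx)), 1e-8)
          expect_lt(max(rel_err(o$rbound,
                                rbound_closed_form(phi, l0, f, kx))), 1e-8)
          expect_lt(max(rel_err(o$rmulti,
                                rmulti_closed_form(phi, l0, f, kx))), 1e-8)
        }
      }
    }
  }
})

test_that("configuration enumeration has the expected combinatorial size", {
  expect_equal(nrow(enumerate_configurations(1, 1, 1)), 2L)
  expect_equal(nrow(enumerate_configurations(2, 1, 1)), 3L)
  # weights over all configurations sum to (l0/kx) * (sum phi)^f
  phi <- compute_phi(1e4, matrix(1e6, 1, 1), 1e-12, 1)
  cfg <- enumerate_configurations(3, 1, 1, phi = phi, l0 = 1e-9,
                                  kx_star = 1e-12)
  expect_equal(sum(cfg$weight), 1e-9 / 1e-12 * sum(phi)^3)
  expect_error(enumerate_configurations(30, 3, 3), "guard")
  expect_error(enumerate_configurations(2.5, 1, 1), "integer")
})

test_that("solved equilibria conserve receptor mass across random instances", {
  set.seed(99)
  worst <- 0
  for (i in 1:300) {
    nl <- sample(1:3, 1); nr <- sample(1:4, 1)
    comp <- stats::runif(nl); comp <- comp / sum(comp)
    ka <- matrix(10^stats::runif(nl * nr, 3, 8), nl, nr)
    pool <- receptor_pool("x", 10^stats::runif(nr, 3, 6))
    mix <- complex_mixture(10^stats::runif(1, -11, -8),
                           stats::runif(1, 1, 40), comp,
                           10^stats::runif(1, -14, -11))
    eq <- solve_equilibrium(pool, mix, ka)
    r <- eq$receptors
    worst <- max(worst, max(abs(r$req + r$rbound - r$rtot) /
                              pmax(r$rtot, 1e-300)))
    expect_true(all(r$req >= 0 & r$req <= r$rtot))
    expect_true(all(r$rmulti >= -1e-12 & r$rmulti <= r$rbound + 1e-9))
    expect_gte(eq$lbound, 0)
  }
  expect_lt(worst, 1e-6)
})

test_that("equilibrium limits: no ligand, monovalent closed form", {
  ka <- matrix(c(1e6, 2e5), 1, 2)
  eq0 <- solve_equilibrium(receptor_pool("x", c(1e5, 2e5)),
                           complex_mixture(0, 4, 1), ka)
  expect_equal(eq0$receptors$req, c(1e5, 2e5))
  expect_equal(eq0$receptors$rbound, c(0, 0))
  expect_equal(eq0$lbound, 0)

  # f = 1, single ligand and receptor: linear mass balance solves exactly
  l0 <- 2e-9; ka1 <- 5e6; rtot <- 1e5
  eq1 <- solve_equilibrium(receptor_pool("x", rtot),
                           complex_mixture(l0, 1, 1),
                           matrix(ka1, 1, 1))
  expect_equal(eq1$receptors$req, rtot / (1 + ka1 * l0), tolerance = 1e-9)
  expect_equal(eq1$receptors$rmulti, 0)
})

test_that("binding is monotone in affinity, ligand and valency", {
  l0 <- 1e-9; kx <- default_kx_star; rtot <- 2e5
  lb <- function(ka, l0_ = l0, f = 4) {
    eq <- solve_equilibrium(receptor_pool("x", rtot),
                            complex_mixture(l0_, f, 1, kx),
                            matrix(ka, 1, 1))
    eq$lbound
  }
  kas <- 10^seq(4, 8, length.out = 15)
  vals <- vapply(kas, lb, 0)
  expect_true(all(diff(vals) > 0))
  l0s <- 10^seq(-11, -8, length.out = 10)
  vals_l <- vapply(l0s, function(l) lb(1e6, l0_ = l), 0)
  expect_true(all(diff(vals_l) > 0))
  # higher valency binds at least as much, for a spread of affinities
  for (ka in c(1e4, 1e5, 1e6, 1e7)) {
    expect_gte(lb(ka, f = 33), lb(ka, f = 4))
  }
})

test_that("two-ligand composition sweeps are continuous with exact pure endpoints", {
  ka <- matrix(c(5e6, 3e5), 2, 1) # two ligands, one receptor
  pool <- receptor_pool("x", 2e5)
  sweep <- seq(0, 1, by = 0.05)
  lb <- vapply(sweep, function(c1) {
    solve_equilibrium(pool, complex_mixture(1e-9, 4, c(c1, 1 - c1)),
                      ka)$lbound
  }, 0)
  pure1 <- solve_equilibrium(pool, complex_mixture(1e-9, 4, 1),
                             matrix(5e6, 1, 1))$lbound
  pure2 <- solve_equilibrium(pool, complex_mixture(1e-9, 4, 1),
                             matrix(3e5, 1, 1))$lbound
  expect_equal(lb[length(lb)], pure1, tolerance = 1e-10)
  expect_equal(lb[1], pure2, tolerance = 1e-10)
  expect_true(all(diff(lb) > 0)) # monotone between the pure endpoints here
  expect_lt(max(abs(diff(lb))) / max(lb), 0.2) # no jumps
})
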