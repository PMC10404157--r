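# shared fixtures: a small two-receptor screen for fast inference tests and
# oracle helpers for the configuration-enumeration checks

small_receptors <- c("FcgRI", "FcgRIIB-232I")

small_affinities <- function() {
  dplyr::filter(documented_affinities(), receptor %in% small_receptors)
}

small_truth <- function(seed = 1L, noise_cv = 0.2) {
  binding_ground_truth(
    seed = seed, noise_cv = noise_cv,
    affinities = small_affinities(),
    expression = c("FcgRI" = 1.5e5, "FcgRIIB-232I" = 2e5)
  )
}

small_screen <- function(seed = 1L, noise_cv = 0.2,
                         subclasses = igg_subclasses) {
  truth <- small_truth(seed = seed, noise_cv = noise_cv)
  design <- generate_design(receptors = small_receptors,
                            subclasses = subclasses)
  simulate_binding_screen(truth, design, seed = seed, noise_cv = noise_cv)
}

small_priors <- function(seed = 1L) {
  build_priors(small_affinities(),
               simulate_expression_replicates(small_truth(seed), seed = seed))
}

quick_config <- function(regime = "fit_affinity", seed = 1L) {
  fit_config(regime = regime, chains = 2, draws = 200, warmup = 300,
             thin = 2, seed = seed)
}

# brute-force macroscopic quantities from the enumerated configurations
oracle_sums <- function(phi, l0, f, kx_star) {
  cfg <- enumerate_configurations(f, nrow(phi), ncol(phi) - 1L, phi = phi,
                                  l0 = l0, kx_star = kx_star)
  rb <- attr(cfg, "receptor_bonds")
  list(
    lbound = sum(cfg$weight[cfg$bonds >= 1]),
    rbound = colSums(rb * cfg$weight),
    rmulti = colSums(rb * cfg$weight * (cfg$bonds >= 2))
  )
}

rel_err <- function(a, b) {
  denom <- pmax(abs(a), abs(b))
  ifelse(denom == 0, 0, abs(a - b) / denom)
}
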