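#' Default crosslinking constant
#'
#' Crosslinking constant \eqn{K_x^*} (quoted in cell·M) governing the
#' propensity of a cell-bound immune complex to engage additional receptors:
#' every binding event after the first has association constant
#' \eqn{K_x^* K_{a,ij}}. The default, 6.31e-13, is the literature estimate
#' for TNP-BSA immune complexes on CHO cells. The unit is treated as an
#' opaque scale throughout: the only dimensional contract is that
#' \eqn{\varphi_{ij} = R_{eq,j} K_{a,ij} K_x^* C_i} is dimensionless.
#'
#' @export
default_kx_star <- 6.31e-13

#' Build an affinity matrix from a tidy affinity table
#'
#' @param tbl data frame with columns `ligand`, `receptor`, `ka` (monovalent
#'   association constants, 1/M). One row per (ligand, receptor) pair.
#' @return numeric matrix, ligands in rows, receptors in columns.
#' @examples
#' tbl <- tibble::tibble(
#'   ligand = c("IgG1", "IgG1"), receptor = c("R1", "R2"), ka = c(1e6, 1e5)
#' )
#' affinity_matrix(tbl)
#' @export
affinity_matrix <- function(tbl) {
  stopifnot(all(c("ligand", "receptor", "ka") %in% names(tbl)))
  if (any(!is.finite(tbl$ka)) || any(tbl$ka < 0)) {
    rlang::abort("all affinities must be finite and >= 0")
  }
  ligands <- unique(tbl$ligand)
  receptors <- unique(tbl$receptor)
  ka <- matrix(NA_real_, length(ligands), length(receptors),
               dimnames = list(ligands, receptors))
  ka[cbind(match(tbl$ligand, ligands), match(tbl$receptor, receptors))] <- tbl$ka
  if (anyNA(ka)) rlang::abort("affinity table is not complete over ligand x receptor")
  ka
}

#' Describe an immune-complex preparation
#'
#' A mixed immune complex is characterised by its molar concentration `l0`,
#' effective valency `f` (possibly non-integer; the fitted engagement
#' capacity of the complex), the monomer composition simplex and the
#' crosslinking constant.
#'
#' @param l0 complex concentration (M), >= 0.
#' @param f effective valency, > 0 (real-valued).
#' @param composition numeric vector of monomer proportions, summing to 1.
#' @param kx_star crosslinking constant, > 0.
#' @return a `complex_mixture` list.
#' @export
complex_mixture <- function(l0, f, composition, kx_star = default_kx_star) {
  if (l0 < 0) rlang::abort("l0 must be >= 0")
  if (f <= 0) rlang::abort("f must be > 0")
  if (kx_star <= 0) rlang::abort("kx_star must be > 0")
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-12) {
    rlang::abort("composition must be a simplex (Ci >= 0, sum Ci = 1)")
  }
  structure(list(l0 = l0, f = f, composition = composition,
                 kx_star = kx_star), class = "complex_mixture")
}

#' Describe the receptor complement of a cell
#'
#' @param cell_label character label for the cell or cell line.
#' @param rtot named numeric vector of total receptor numbers per cell, >= 0.
#' @return a `receptor_pool` list.
#' @export
receptor_pool <- function(cell_label, rtot) {
  if (any(rtot < 0)) rlang::abort("rtot must be >= 0")
  structure(list(cell_label = cell_label, rtot = rtot),
            class = "receptor_pool")
}

#' Per-(ligand, receptor) binding propensity matrix
#'
#' Computes the dimensionless matrix \eqn{\varphi} that the closed-form
#' macroscopic quantities are expressed in: \eqn{\varphi_{ij} =
#' R_{eq,j} K_{a,ij} K_x^* C_i} for receptor columns, and
#' \eqn{\varphi_{i0} = C_i} for the unbound slot (first column).
#'
#' @param req free-receptor numbers at equilibrium (length NR).
#' @param ka affinity matrix (NL x NR), 1/M.
#' @param kx_star crosslinking constant.
#' @param composition monomer composition simplex (length NL).
#' @return NL x (NR + 1) matrix; first column is the unbound slot.
#' @export
compute_phi <- function(req, ka, kx_star, composition) {
  ka <- as.matrix(ka)
  if (length(req) != ncol(ka) || length(composition) != nrow(ka)) {
    rlang::abort("dimension mismatch between req, ka and composition")
  }
  if (any(req < 0) || any(ka < 0) || kx_star <= 0 || any(composition < 0)) {
    rlang::abort("inputs to compute_phi must be nonnegative (kx_star > 0)")
  }
  phi <- cbind(composition,
               composition * ka * kx_star * rep(req, each = nrow(ka)))
  colnames(phi) <- c("unbound",
                     colnames(ka) %||% paste0("R", seq_len(ncol(ka))))
  rownames(phi) <- rownames(ka)
  phi
}

#' Closed-form amount of cell-bound complexes
#'
#' Total relative number of complexes engaging at least one receptor:
#' \eqn{L_{bound} = (L_0/K_x^*)\,[(\sum_{ij}\varphi_{ij})^f - 1]}.
#' Continuous in real-valued `f`.
#'
#' @param phi propensity matrix from [compute_phi()].
#' @param l0 complex concentration (M).
#' @param f effective valency (> 0, real).
#' @param kx_star crosslinking constant (> 0).
#' @export
lbound_closed_form <- function(phi, l0, f, kx_star) {
  if (kx_star <= 0) rlang::abort("kx_star must be > 0")
  if (f <= 0) rlang::abort("f must be > 0")
  l0 / kx_star * (sum(phi)^f - 1)
}

#' Closed-form amount of bound receptor
#'
#' Total relative amount of receptor type `n` engaged by complexes:
#' \eqn{R_{bound,n} = L_0 f / K_x^* (\sum_m \varphi_{mn})
#' (\sum_{ij}\varphi_{ij})^{f-1}}.
#'
#' @inheritParams lbound_closed_form
#' @param n receptor index (1-based, excluding the unbound slot) or `NULL`
#'   for all receptors.
#' @export
rbound_closed_form <- function(phi, l0, f, kx_star, n = NULL) {
  if (kx_star <= 0) rlang::abort("kx_star must be > 0")
  nr <- ncol(phi) - 1L
  if (is.null(n)) n <- seq_len(nr)
  if (any(n < 1L) || any(n > nr)) rlang::abort("invalid receptor index")
  s <- sum(phi)
  l0 * f / kx_star * colSums(phi[, n + 1L, drop = FALSE]) * s^(f - 1)
}

#' Closed-form amount of multimerized receptor
#'
#' Amount of receptor type `n` inside complexes making two or more bonds --
#' the crosslinked, activation-competent fraction:
#' \eqn{R_{multi,n} = L_0 f / K_x^* (\sum_m \varphi_{mn})
#' [(\sum_{ij}\varphi_{ij})^{f-1} - 1]}. Identically zero at valency 1.
#'
#' @inheritParams rbound_closed_form
#' @export
rmulti_closed_form <- function(phi, l0, f, kx_star, n = NULL) {
  if (kx_star <= 0) rlang::abort("kx_star must be > 0")
  nr <- ncol(phi) - 1L
  if (is.null(n)) n <- seq_len(nr)
  if (any(n < 1L) || any(n > nr)) rlang::abort("invalid receptor index")
  s <- sum(phi)
  l0 * f / kx_star * colSums(phi[, n + 1L, drop = FALSE]) * (s^(f - 1) - 1)
}

# Scalar mass-balance solve. Given per-receptor composition-weighted
# affinities A_n = sum_i C_i Ka_in, the mass balance
#   Rtot_n = Req_n (1 + L0 f A_n S^(f-1)),  S = 1 + Kx* sum_n A_n Req_n
# reduces to one monotone scalar equation in S on [1, 1 + Kx* sum A_n Rtot_n].
# Solved by bisection-safeguarded Newton to near machine precision.
.solve_s <- function(a, rtot, l0, f, kx_star, tol = 4e-16,
                     max_iter = 300L) {
  smax <- 1 + kx_star * sum(a * rtot)
  if (smax == 1) return(1)
  h <- function(s) {
    s - 1 - kx_star * sum(a * rtot / (1 + l0 * f * a * s^(f - 1)))
  }
  lo <- 1; hi <- smax
  s <- min(smax, max(1, 1 + kx_star * sum(a * rtot / (1 + l0 * f * a))))
  for (it in seq_len(max_iter)) {
    hs <- h(s)
    if (hs > 0) hi <- s else lo <- s
    # h'(s) >= 1 everywhere, so |h| bounds the distance to the root
    if (hi - lo < tol * hi || abs(hs) < tol * s) break
    if (it %% 2L == 0L) {
      # forced bisection every other step guarantees bracket contraction
      # even where h switches near-discontinuously (large f)
      s <- (lo + hi) / 2
      next
    }
    denom <- 1 + l0 * f * a * s^(f - 1)
    dh <- 1 + kx_star * sum(a * rtot * l0 * f * a * (f - 1) * s^(f - 2) /
                              denom^2)
    s_new <- s - hs / dh
    if (!is.finite(s_new) || s_new <= lo || s_new >= hi) {
      s_new <- (lo + hi) / 2
    }
    s <- s_new
  }
  s
}

# Vectorized single-receptor variant: each element an independent cell with
# one receptor type and composition-weighted affinity a_eff. Used on the
# screen likelihood path where every CHO line expresses one receptor.
.solve_s_vec <- function(a_eff, rtot, l0, f, kx_star,
                         tol = 4e-16, max_iter = 300L) {
  smax <- 1 + kx_star * a_eff * rtot
  lo <- rep(1, length(a_eff)); hi <- smax
  s <- pmin(smax, 1 + kx_star * a_eff * rtot / (1 + l0 * f * a_eff))
  active <- smax > 1
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    denom <- 1 + l0 * f * a_eff * s^(f - 1)
    hs <- s - 1 - kx_star * a_eff * rtot / denom
    hi <- ifelse(active & hs > 0, s, hi)
    lo <- ifelse(active & hs <= 0, s, lo)
    # h'(s) >= 1 everywhere, so |h| bounds the distance to the root
    active <- active & (hi - lo >= tol * hi) & (abs(hs) >= tol * s)
    if (it %% 2L == 0L) {
      s <- ifelse(active, (lo + hi) / 2, s)
      next
    }
    dh <- 1 + kx_star * a_eff * rtot * l0 * f * a_eff * (f - 1) *
      s^(f - 2) / denom^2
    s_new <- s - hs / dh
    bad <- s_new <= lo | s_new >= hi | !is.finite(s_new)
    s_new <- ifelse(bad, (lo + hi) / 2, s_new)
    s <- ifelse(active, s_new, s)
  }
  s
}

#' Solve the multivalent binding equilibrium for one cell
#'
#' Finds the free-receptor numbers `req` satisfying conservation of mass,
#' `rtot = req + rbound(req)`, for a cell exposed to a (possibly mixed)
#' immune-complex preparation, then evaluates all macroscopic bound
#' quantities at the solution. The NR-dimensional balance is reduced exactly
#' to a single monotone scalar equation in the total propensity sum and
#' solved to near machine precision.
#'
#' @param pool a [receptor_pool()].
#' @param mixture a [complex_mixture()].
#' @param affinities affinity matrix (NL x NR) or tidy affinity table.
#' @return object of class `fcr_equilibrium`: list with `receptors`
#'   (tibble: receptor, rtot, req, rbound, rmulti), `lbound`, `phi`, and the
#'   inputs. `tidy()` returns the per-receptor tibble.
#' @examples
#' ka <- matrix(1e6, 1, 1, dimnames = list("IgG1", "R1"))
#' eq <- solve_equilibrium(
#'   receptor_pool("cell", c(R1 = 1e5)),
#'   complex_mixture(1e-9, 4, 1),
#'   ka
#' )
#' eq$lbound
#' @export
solve_equilibrium <- function(pool, mixture, affinities) {
  ka <- if (is.matrix(affinities)) affinities else affinity_matrix(affinities)
  rtot <- pool$rtot
  if (length(rtot) != ncol(ka)) {
    rlang::abort("receptor pool and affinity matrix disagree on NR")
  }
  comp <- mixture$composition
  if (length(comp) != nrow(ka)) {
    rlang::abort("mixture composition and affinity matrix disagree on NL")
  }
  a <- as.numeric(comp %*% ka) # composition-weighted affinity per receptor
  s <- .solve_s(a, rtot, mixture$l0, mixture$f, mixture$kx_star)
  denom <- 1 + mixture$l0 * mixture$f * a * s^(mixture$f - 1)
  req <- rtot / denom
  phi <- compute_phi(req, ka, mixture$kx_star, comp)
  resid <- abs(sum(phi) - s)
  if (resid > 1e-8 * s) {
    rlang::abort(sprintf(
      "equilibrium solve failed to converge (residual %.3e)", resid))
  }
  rbound <- rbound_closed_form(phi, mixture$l0, mixture$f, mixture$kx_star)
  rmulti <- rmulti_closed_form(phi, mixture$l0, mixture$f, mixture$kx_star)
  receptors <- tibble::tibble(
    receptor = colnames(ka) %||% paste0("R", seq_along(rtot)),
    rtot = unname(rtot), req = unname(req),
    rbound = unname(rbound), rmulti = unname(rmulti)
  )
  structure(list(
    receptors = receptors,
    lbound = lbound_closed_form(phi, mixture$l0, mixture$f, mixture$kx_star),
    phi = phi, pool = pool, mixture = mixture
  ), class = "fcr_equilibrium")
}

#' @export
print.fcr_equilibrium <- function(x, ...) {
  cat("<fcr_equilibrium>", x$pool$cell_label,
      sprintf("(f = %g, L0 = %.3g M)\n", x$mixture$f, x$mixture$l0))
  cat(sprintf("  lbound = %.6g\n", x$lbound))
  print(x$receptors)
  invisible(x)
}

#' @rdname solve_equilibrium
#' @param x an `fcr_equilibrium` object.
#' @param ... unused.
#' @exportS3Method
tidy.fcr_equilibrium <- function(x, ...) x$receptors

# all nonnegative integer vectors of length k summing to f, as rows
.compositions_of <- function(f, k) {
  if (k == 1L) return(matrix(f, 1L, 1L))
  out <- vector("list", f + 1L)
  for (first in 0:f) {
    rest <- .compositions_of(f - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Enumerate all binding configurations of an integer-valency complex
#'
#' Exhaustive enumeration of the configuration vectors `q` (per-ligand bond
#' counts to each receptor plus per-ligand unbound slots) of a complex with
#' integer valency `f_int`, together with each configuration's equilibrium
#' relative abundance \eqn{v_{q,eq} = \binom{f}{q} (L_0/K_x^*) \prod
#' \varphi^{q}}. This is the brute-force counterpart of the closed-form
#' expressions and exists to verify them: summing weights over configurations
#' with at least one bond reproduces `lbound_closed_form`, weighting bond
#' counts reproduces `rbound_closed_form`, and restricting to configurations
#' with two or more bonds reproduces `rmulti_closed_form`.
#'
#' @param f_int positive integer valency.
#' @param nl,nr numbers of ligand and receptor species.
#' @param phi optional NL x (NR+1) propensity matrix (unbound slot first);
#'   when given, weights are attached.
#' @param l0,kx_star scale constants used in the weights.
#' @param max_configurations guard on the enumeration size.
#' @return tibble with one row per configuration: `bonds` (total bound
#'   monomers) and, when `phi` is supplied, `weight`. The raw configuration
#'   matrix is in attribute `"q"` (slots ordered ligand-major, unbound slot
#'   first within each ligand) and per-receptor bond counts in attribute
#'   `"receptor_bonds"`.
#' @export
enumerate_configurations <- function(f_int, nl, nr, phi = NULL,
                                     l0 = 1, kx_star = 1,
                                     max_configurations = 1e6) {
  if (f_int < 1 || f_int != round(f_int)) {
    rlang::abort("f_int must be a positive integer")
  }
  k <- nl * (nr + 1L)
  n_config <- choose(f_int + k - 1, k - 1)
  if (n_config > max_configurations) {
    rlang::abort(sprintf(
      "enumeration would produce %.3g configurations (guard: %.0g)",
      n_config, max_configurations))
  }
  q <- .compositions_of(f_int, k)
  # slot (i, j): column (i-1)*(nr+1) + j + 1; j = 0 is the unbound slot
  unbound_cols <- (seq_len(nl) - 1L) * (nr + 1L) + 1L
  bonds <- f_int - rowSums(q[, unbound_cols, drop = FALSE])
  receptor_bonds <- sapply(seq_len(nr), function(j) {
    rowSums(q[, (seq_len(nl) - 1L) * (nr + 1L) + j + 1L, drop = FALSE])
  })
  receptor_bonds <- matrix(receptor_bonds, nrow = nrow(q), ncol = nr)
  out <- tibble::tibble(bonds = as.integer(bonds))
  if (!is.null(phi)) {
    log_phi <- log(t(phi)) # slot order matches q columns (ligand-major)
    lp <- as.numeric(log_phi)
    contrib <- q * rep(lp, each = nrow(q))
    contrib[q == 0] <- 0 # 0 * log(0) := 0
    log_coef <- lgamma(f_int + 1) - rowSums(lgamma(q + 1))
    out$weight <- l0 / kx_star * exp(log_coef + rowSums(contrib))
  }
  attr(out, "q") <- q
  attr(out, "receptor_bonds") <- receptor_bonds
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
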