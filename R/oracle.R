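#' Synthetic torsional potential specification
#'
#' An analytic stand-in for the constrained quantum-chemistry
#' calculations that supply intramolecular energies in crystal structure
#' prediction. The energy over independent torsions `theta` (degrees)
#' and dependent degrees of freedom `beta` (unitless) is
#' \deqn{E(\theta, \beta) = c_0
#'   + \sum V_{ik} (1 - \cos(k \theta_i + \phi_{ik}))
#'   + \sum W_{ij} \cos(k_i \theta_i + \phi_i) \cos(k_j \theta_j + \phi_j)
#'   + \sum_i \tfrac12 q_i (\theta_i - \theta^0_i)^2
#'   + \sum_m \tfrac12 \kappa_m (\beta_m - \hat\beta_m(\theta))^2}
#' with dependent-coordinate targets
#' \eqn{\hat\beta_m(\theta) = \beta^0_m + \sum s \sin(k \theta_i + \psi)}.
#' The harmonic dependent model makes the constrained minimum analytic:
#' \eqn{\beta^*(\theta) = \hat\beta(\theta)}, so LAM-construction tests
#' have closed forms. The optional pure-quadratic terms (`quadratic`)
#' break 360-degree periodicity and are intended for bounded domains
#' only.
#'
#' @param n_indep number of independent torsions.
#' @param n_dep number of dependent degrees of freedom.
#' @param fourier data frame with columns `dim`, `mult` (integer
#'   multiplicity), `barrier` (kJ/mol, may be negative for shape terms)
#'   and `phase` (degrees). May be empty.
#' @param coupling data frame with columns `dim_i`, `dim_j`, `amp`
#'   (kJ/mol), `mult_i`, `mult_j`, `phase_i`, `phase_j`. May be empty.
#' @param dep list with one entry per dependent coordinate, each a list
#'   `list(beta0 =, terms = data.frame(dim, slope, mult, phase))`.
#' @param kappa numeric vector of positive harmonic stiffnesses
#'   (kJ/mol per unit squared), one per dependent coordinate.
#' @param quadratic `NULL`, or `list(theta0 =, curvature =)` with one
#'   value per independent torsion (curvature in kJ/mol/deg^2; use 0 for
#'   dimensions without a quadratic term).
#' @param const constant energy offset (kJ/mol).
#' @param id identifier string carried into LAM-set provenance.
#' @return An object of class `potential_spec`.
#' @seealso [preset_potential()], [random_spec()], [constrained_minimize()]
#' @export
potential_spec <- function(n_indep, n_dep = 0, fourier = NULL,
                           coupling = NULL, dep = list(), kappa = numeric(),
                           quadratic = NULL, const = 0,
                           id = "potential") {
  empty_f <- data.frame(dim = integer(), mult = integer(),
                        barrier = numeric(), phase = numeric())
  empty_c <- data.frame(dim_i = integer(), dim_j = integer(),
                        amp = numeric(), mult_i = integer(),
                        mult_j = integer(), phase_i = numeric(),
                        phase_j = numeric())
  if (is.null(fourier)) fourier <- empty_f
  if (is.null(coupling)) coupling <- empty_c
  fourier <- as.data.frame(fourier); coupling <- as.data.frame(coupling)
  stopifnot(all(c("dim", "mult", "barrier", "phase") %in% names(fourier)),
            all(names(empty_c) %in% names(coupling)))
  if (length(dep) != n_dep || length(kappa) != n_dep)
    stop("dep and kappa must have one entry per dependent coordinate")
  if (any(kappa <= 0))
    stop("all dependent-DOF stiffnesses kappa must be positive")
  if (nrow(fourier) && any(fourier$dim < 1 | fourier$dim > n_indep))
    stop("fourier term references a dimension outside 1..n_indep")
  if (nrow(coupling) &&
      any(c(coupling$dim_i, coupling$dim_j) < 1 |
          c(coupling$dim_i, coupling$dim_j) > n_indep))
    stop("coupling term references a dimension outside 1..n_indep")
  if (!is.null(quadratic)) {
    quadratic$theta0 <- rep_len(as.numeric(quadratic$theta0), n_indep)
    quadratic$curvature <- rep_len(as.numeric(quadratic$curvature), n_indep)
  }
  structure(list(n_indep = as.integer(n_indep), n_dep = as.integer(n_dep),
                 fourier = fourier, coupling = coupling, dep = dep,
                 kappa = as.numeric(kappa), quadratic = quadratic,
                 const = as.numeric(const), id = as.character(id)),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic torsional potential '%s': %d torsion(s), %d dependent DOF(s)\n",
    x$id, x$n_indep, x$n_dep))
  cat(sprintf("  %d Fourier term(s), %d coupling term(s)%s\n",
              nrow(x$fourier), nrow(x$coupling),
              if (!is.null(x$quadratic)) ", quadratic terms present" else ""))
  invisible(x)
}

DEG <- pi / 180

as_theta_matrix <- function(theta, n) {
  if (!is.matrix(theta)) theta <- matrix(theta, ncol = n, byrow = FALSE)
  if (ncol(theta) != n)
    stop(sprintf("theta has %d column(s) but the potential has %d torsion(s)",
                 ncol(theta), n))
  theta
}

#' Relaxed intramolecular energy surface
#'
#' Energy at the constrained minimum over the dependent degrees of
#' freedom, `E_min(theta) = E(theta, beta_hat(theta))`, evaluated in
#' closed form. This is the surface whose derivatives define a LAM.
#'
#' @param spec a [potential_spec()].
#' @param theta numeric vector (one conformation) or matrix with one
#'   conformation per row, degrees.
#' @return numeric vector of energies (kJ/mol), one per conformation.
#' @export
relaxed_energy <- function(spec, theta) {
  th <- as_theta_matrix(theta, spec$n_indep)
  e <- rep(spec$const, nrow(th))
  f <- spec$fourier
  for (t in seq_len(nrow(f)))
    e <- e + f$barrier[t] *
      (1 - cos(DEG * (f$mult[t] * th[, f$dim[t]] + f$phase[t])))
  cp <- spec$coupling
  for (t in seq_len(nrow(cp)))
    e <- e + cp$amp[t] *
      cos(DEG * (cp$mult_i[t] * th[, cp$dim_i[t]] + cp$phase_i[t])) *
      cos(DEG * (cp$mult_j[t] * th[, cp$dim_j[t]] + cp$phase_j[t]))
  if (!is.null(spec$quadratic)) {
    q <- spec$quadratic
    e <- e + 0.5 * colSums(q$curvature * (t(th) - q$theta0)^2)
  }
  e
}

# analytic gradient of the relaxed surface, kJ/mol/deg; matrix rows =
# conformations
relaxed_gradient <- function(spec, theta) {
  th <- as_theta_matrix(theta, spec$n_indep)
  g <- matrix(0, nrow(th), spec$n_indep)
  f <- spec$fourier
  for (t in seq_len(nrow(f)))
    g[, f$dim[t]] <- g[, f$dim[t]] + f$barrier[t] * f$mult[t] * DEG *
      sin(DEG * (f$mult[t] * th[, f$dim[t]] + f$phase[t]))
  cp <- spec$coupling
  for (t in seq_len(nrow(cp))) {
    ci <- cos(DEG * (cp$mult_i[t] * th[, cp$dim_i[t]] + cp$phase_i[t]))
    cj <- cos(DEG * (cp$mult_j[t] * th[, cp$dim_j[t]] + cp$phase_j[t]))
    si <- sin(DEG * (cp$mult_i[t] * th[, cp$dim_i[t]] + cp$phase_i[t]))
    sj <- sin(DEG * (cp$mult_j[t] * th[, cp$dim_j[t]] + cp$phase_j[t]))
    g[, cp$dim_i[t]] <- g[, cp$dim_i[t]] -
      cp$amp[t] * cp$mult_i[t] * DEG * si * cj
    g[, cp$dim_j[t]] <- g[, cp$dim_j[t]] -
      cp$amp[t] * cp$mult_j[t] * DEG * ci * sj
  }
  if (!is.null(spec$quadratic)) {
    q <- spec$quadratic
    g <- g + t(q$curvature * (t(th) - q$theta0))
  }
  g
}

#' Dependent-coordinate target values
#'
#' The smooth targets \eqn{\hat\beta_m(\theta)} about which each
#' dependent coordinate is harmonically restrained; for this potential
#' family they are also the exact constrained-minimum values
#' \eqn{\beta^*(\theta)}. Target terms with multiplicity 0 are linear,
#' `slope * theta_dim` (used by the bounded-domain quadratic preset);
#' all others are sinusoidal, `slope * sin(mult * theta_dim + phase)`.
#'
#' @inheritParams relaxed_energy
#' @return numeric matrix, one row per conformation, one column per
#'   dependent coordinate (a vector for a single conformation).
#' @export
beta_hat <- function(spec, theta) {
  th <- as_theta_matrix(theta, spec$n_indep)
  out <- matrix(0, nrow(th), spec$n_dep)
  for (m in seq_len(spec$n_dep)) {
    dm <- spec$dep[[m]]
    v <- rep(dm$beta0, nrow(th))
    tr <- dm$terms
    for (t in seq_len(nrow(tr)))
      v <- v + if (tr$mult[t] == 0) tr$slope[t] * th[, tr$dim[t]]
               else tr$slope[t] *
                 sin(DEG * (tr$mult[t] * th[, tr$dim[t]] + tr$phase[t]))
    out[, m] <- v
  }
  if (!is.matrix(theta)) out <- drop(out)
  out
}

#' Full oracle energy
#'
#' Closed-form evaluation of `E(theta, beta)` including the harmonic
#' penalty of the dependent coordinates away from their targets.
#'
#' @inheritParams relaxed_energy
#' @param beta numeric vector of dependent-coordinate values (length
#'   `n_dep`).
#' @return energy in kJ/mol.
#' @export
potential_energy <- function(spec, theta, beta = numeric()) {
  if (length(beta) != spec$n_dep)
    stop(sprintf("beta has length %d but the potential has %d dependent DOF(s)",
                 length(beta), spec$n_dep))
  e <- relaxed_energy(spec, theta)
  if (spec$n_dep) {
    bh <- beta_hat(spec, theta)
    if (!is.matrix(bh)) bh <- matrix(bh, ncol = spec$n_dep)
    dev <- sweep(bh, 2, beta)        # beta_hat - beta, row-wise
    e <- e + 0.5 * as.numeric(dev^2 %*% spec$kappa)
  }
  e
}

#' Constrained minimization over the dependent coordinates
#'
#' Minimizes `E(theta, beta)` over `beta` at fixed `theta`. For this
#' harmonic potential family the minimizer is analytic,
#' `beta* = beta_hat(theta)`, and the reported gradient over `beta`
#' vanishes identically; the convergence report exists so that external
#' quantum-chemistry adapters can honour the same contract.
#'
#' @param spec a [potential_spec()].
#' @param theta torsion vector (degrees).
#' @param tol gradient tolerance recorded in the convergence report.
#' @return list with `e_min` (kJ/mol), `beta_star`, `gradient`
#'   (dE_min/dtheta, kJ/mol/deg) and `convergence`.
#' @export
constrained_minimize <- function(spec, theta, tol = 1e-9) {
  theta <- as.numeric(theta)
  if (length(theta) != spec$n_indep)
    stop(sprintf("theta has length %d but the potential has %d torsion(s)",
                 length(theta), spec$n_indep))
  bs <- if (spec$n_dep) beta_hat(spec, theta) else numeric()
  list(e_min = relaxed_energy(spec, theta),
       beta_star = as.numeric(bs),
       gradient = drop(relaxed_gradient(spec, theta)),
       convergence = list(converged = TRUE, method = "analytic",
                          grad_norm = 0, tol = tol))
}

#' Unconstrained global minimum energy
#'
#' Locates `U_global`, the lowest relaxed energy over the domain. A
#' dense vectorized pre-scan (capped at about 50,000 points, resolution
#' shared evenly across dimensions) identifies the lowest basins; its
#' best points, plus seeded uniform random starts, are polished with
#' L-BFGS-B using the analytic gradient. The pre-scan makes the search
#' reliable on corrugated surfaces where gradient descent from a coarse
#' start can stall in a local wrinkle. All conformational energies
#' entering LAMs are referenced to this constant, so that
#' `deltaE_intra >= 0` at the located minimum.
#'
#' @param spec a [potential_spec()].
#' @param d a [torsion_domain()] bounding the search.
#' @param n_starts number of random starts added to the pre-scan starts.
#' @param seed integer seed for the random starts (local RNG stream;
#'   the caller's RNG state is untouched).
#' @param scan_budget cap on the number of pre-scan points.
#' @return list with `u_global` (kJ/mol) and `theta_min` (canonical).
#' @export
global_minimum <- function(spec, d, n_starts = 50, seed = 1,
                           scan_budget = 50000) {
  n <- spec$n_indep
  if (domain_dim(d) != n)
    stop("domain dimension does not match the potential")
  per_dim <- max(4L, floor(scan_budget^(1 / n)))
  axes <- lapply(seq_len(n), function(i)
    seq(d$lower[i], d$upper[i], length.out = per_dim + 1L)[seq_len(per_dim)])
  dense <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  e_dense <- relaxed_energy(spec, dense)
  starts <- dense[order(e_dense)[seq_len(min(20L, nrow(dense)))], ,
                  drop = FALSE]
  rand <- with_local_seed(seed, {
    matrix(stats::runif(n_starts * n, rep(d$lower, each = n_starts),
                        rep(d$upper, each = n_starts)),
           ncol = n)
  })
  starts <- rbind(starts, rand)
  lo <- ifelse(d$periodic, d$lower - 360, d$lower)
  hi <- ifelse(d$periodic, d$upper + 360, d$upper)
  best <- list(value = Inf, par = starts[1, ])
  fn <- function(x) relaxed_energy(spec, matrix(x, nrow = 1))
  gr <- function(x) drop(relaxed_gradient(spec, matrix(x, nrow = 1)))
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], fn, gr, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(res) && res$value < best$value) best <- res
  }
  list(u_global = best$value,
       theta_min = canonicalize(best$par, d))
}

# evaluate a seeded expression without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Randomized synthetic potential
#'
#' Draws a reproducible potential with 1-3 Fourier terms per torsion
#' (multiplicities 1-3, barriers uniform in `barrier_range`, uniform
#' phases), product-coupling terms between random dimension pairs with
#' probability `coupling_density` per pair (amplitudes uniform in
#' `0.5..0.4 * max(barrier_range)`, multiplicities 1-2), and harmonic
#' dependent coordinates with 1-2 sinusoidal target terms each
#' (stiffness uniform in 0.5..3). Any nonzero coupling density makes
#' the surface non-separable, which in practice yields multiple minima.
#'
#' @param seed integer; the same seed always returns the same spec.
#' @param n_indep,n_dep counts of independent torsions and dependent
#'   coordinates.
#' @param barrier_range positive two-vector of Fourier barrier bounds
#'   (kJ/mol).
#' @param coupling_density probability in `[0, 1]` of a coupling term
#'   for each unordered dimension pair.
#' @return a [potential_spec()] with id `random:<seed>`.
#' @export
random_spec <- function(seed, n_indep = 2, n_dep = 1,
                        barrier_range = c(1, 8), coupling_density = 0.5) {
  stopifnot(all(barrier_range > 0), coupling_density >= 0,
            coupling_density <= 1)
  with_local_seed(seed, {
    f <- do.call(rbind, lapply(seq_len(n_indep), function(i) {
      k <- sample.int(3, sample.int(3, 1))
      data.frame(dim = i, mult = k,
                 barrier = stats::runif(length(k), barrier_range[1],
                                        barrier_range[2]),
                 phase = stats::runif(length(k), 0, 360))
    }))
    cp <- NULL
    if (n_indep >= 2) {
      pairs <- utils::combn(n_indep, 2)
      keep <- stats::runif(ncol(pairs)) < coupling_density
      if (any(keep)) {
        pairs <- pairs[, keep, drop = FALSE]
        cp <- data.frame(
          dim_i = pairs[1, ], dim_j = pairs[2, ],
          amp = stats::runif(ncol(pairs), 0.5,
                             max(1, 0.4 * max(barrier_range))),
          mult_i = sample.int(2, ncol(pairs), replace = TRUE),
          mult_j = sample.int(2, ncol(pairs), replace = TRUE),
          phase_i = stats::runif(ncol(pairs), 0, 360),
          phase_j = stats::runif(ncol(pairs), 0, 360))
      }
    }
    dep <- lapply(seq_len(n_dep), function(m) {
      nt <- sample.int(2, 1)
      list(beta0 = stats::rnorm(1, 0, 0.5),
           terms = data.frame(
             dim = sample.int(n_indep, nt, replace = TRUE),
             slope = stats::runif(nt, 0.1, 0.5),
             mult = sample.int(2, nt, replace = TRUE),
             phase = stats::runif(nt, 0, 360)))
    })
    kappa <- stats::runif(n_dep, 0.5, 3)
    potential_spec(n_indep, n_dep, fourier = f, coupling = cp, dep = dep,
                   kappa = kappa, id = paste0("random:", seed))
  })
}
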