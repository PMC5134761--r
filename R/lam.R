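#' Construct a Local Approximate Model
#'
#' Builds a second-order model of the relaxed intramolecular energy
#' surface about a reference conformation, together with a linear model
#' of the dependent coordinates:
#' \deqn{\Delta E(\theta) \approx E_{ref} + b \cdot \Delta\theta
#'   + \tfrac12 \Delta\theta^T A \Delta\theta, \qquad
#'   \beta(\theta) \approx \beta_{ref} + C \Delta\theta}
#' where `E_ref` is the constrained-minimum energy at `theta_ref`
#' referenced to the molecule-wide global minimum `u_global`. The
#' gradient `b` and curvature `A` are central finite differences of the
#' *relaxed* surface (dependent coordinates re-minimized at every
#' stencil point, so their relaxation is folded into the model), with
#' diagonal second derivatives from the 3-point stencil and
#' off-diagonals from the 4-point cross stencil; `A` is symmetrized.
#' The sensitivity matrix `C` is a central difference of the
#' constrained-minimum dependent values. Stencil points may fall
#' slightly outside the domain near non-periodic edges; the analytic
#' oracle is defined there, mirroring how constrained quantum-chemistry
#' calculations can step just past a search boundary.
#'
#' A reference energy below `-1e-6` kJ/mol aborts (it indicates a wrong
#' `u_global`); small negatives from finite-difference noise are clamped
#' to zero with a warning.
#'
#' @param spec a [potential_spec()] oracle.
#' @param theta_ref canonical reference conformation (degrees).
#' @param d the [torsion_domain()].
#' @param u_global the unconstrained global-minimum energy (kJ/mol);
#'   see [global_minimum()].
#' @param fd_step finite-difference step in degrees (default 1).
#' @param payload opaque metadata list carried with the model (for
#'   example a level-of-theory tag or point charges); never interpreted.
#' @return an object of class `lam` with fields `theta_ref`, `e_ref`,
#'   `b`, `A`, `beta_ref`, `C`, `payload`.
#' @export
build_lam <- function(spec, theta_ref, d, u_global, fd_step = 1,
                      payload = list()) {
  theta_ref <- canonicalize(theta_ref, d)
  n <- spec$n_indep
  if (domain_dim(d) != n) stop("domain dimension does not match the potential")
  if (any(!d$periodic & (theta_ref < d$lower - 1e-9 |
                         theta_ref > d$upper + 1e-9)))
    stop("theta_ref lies outside the domain")
  h <- fd_step
  e0 <- relaxed_energy(spec, theta_ref)

  # +/- h stencil along each axis, evaluated in one vectorized call
  plus <- minus <- matrix(theta_ref, n, n, byrow = TRUE)
  diag(plus) <- diag(plus) + h
  diag(minus) <- diag(minus) - h
  ep <- relaxed_energy(spec, plus)
  em <- relaxed_energy(spec, minus)
  b <- (ep - em) / (2 * h)
  A <- diag(as.numeric((ep - 2 * e0 + em) / h^2), n)

  if (n > 1) {
    idx <- utils::combn(n, 2)
    cross <- matrix(theta_ref, 4 * ncol(idx), n, byrow = TRUE)
    for (q in seq_len(ncol(idx))) {
      i <- idx[1, q]; j <- idx[2, q]; r <- (q - 1) * 4
      cross[r + 1, c(i, j)] <- cross[r + 1, c(i, j)] + c(h, h)
      cross[r + 2, c(i, j)] <- cross[r + 2, c(i, j)] + c(h, -h)
      cross[r + 3, c(i, j)] <- cross[r + 3, c(i, j)] + c(-h, h)
      cross[r + 4, c(i, j)] <- cross[r + 4, c(i, j)] + c(-h, -h)
    }
    ec <- relaxed_energy(spec, cross)
    for (q in seq_len(ncol(idx))) {
      i <- idx[1, q]; j <- idx[2, q]; r <- (q - 1) * 4
      A[i, j] <- A[j, i] <-
        (ec[r + 1] - ec[r + 2] - ec[r + 3] + ec[r + 4]) / (4 * h^2)
    }
  }
  A <- (A + t(A)) / 2

  beta_ref <- if (spec$n_dep) beta_hat(spec, theta_ref) else numeric()
  C <- matrix(0, spec$n_dep, n)
  if (spec$n_dep) {
    bp <- beta_hat(spec, plus); bm <- beta_hat(spec, minus)
    if (!is.matrix(bp)) { bp <- matrix(bp, ncol = 1); bm <- matrix(bm, ncol = 1) }
    C <- t(bp - bm) / (2 * h)           # rows = dependent DOFs
  }

  e_ref <- e0 - u_global
  if (e_ref < -1e-6)
    stop(sprintf(
      "reference energy %.3g kJ/mol is below the global minimum; u_global is wrong",
      e_ref))
  if (e_ref < 0) {
    warning(sprintf(
      "clamping small negative reference energy %.3g kJ/mol to 0", e_ref))
    e_ref <- 0
  }
  structure(list(theta_ref = as.numeric(theta_ref), e_ref = e_ref,
                 b = as.numeric(b), A = A,
                 beta_ref = as.numeric(beta_ref), C = C,
                 payload = payload),
            class = "lam")
}

#' @export
print.lam <- function(x, ...) {
  cat(sprintf("LAM at (%s) deg: E_ref = %.6g kJ/mol, |b| = %.4g kJ/mol/deg\n",
              paste(signif(x$theta_ref, 6), collapse = ", "),
              x$e_ref, sqrt(sum(x$b^2))))
  invisible(x)
}

#' Evaluate one LAM at a conformation
#'
#' Second-order prediction of the conformational energy and linear
#' prediction of the dependent coordinates, with the displacement taken
#' per dimension along the shorter arc for periodic dimensions.
#'
#' @param lam a [build_lam()] object.
#' @param theta canonical torsion vector (degrees).
#' @param d the [torsion_domain()].
#' @return list with `energy` (kJ/mol) and `beta`.
#' @export
evaluate_lam <- function(lam, theta, d) {
  theta <- check_dim(theta, d)
  delta <- angle_delta(lam$theta_ref, theta, d)
  list(energy = lam$e_ref + sum(lam$b * delta) +
         0.5 * sum(delta * (lam$A %*% delta)),
       beta = as.numeric(lam$beta_ref + lam$C %*% delta))
}

#' Create a LAM set
#'
#' A collection of LAMs over one domain, the unit of serialization. The
#' provenance records the oracle identity, the global-minimum reference
#' energy, and the build parameters.
#'
#' @param d a [torsion_domain()].
#' @param lams list of [build_lam()] objects.
#' @param oracle_id identifier of the oracle the models were built from.
#' @param u_global the reference energy the models share (kJ/mol).
#' @param build_params list of build settings (fd step, tolerances, ...).
#' @return an object of class `lam_set`.
#' @export
lam_set <- function(d, lams = list(), oracle_id = "unknown",
                    u_global = 0, build_params = list(fd_step = 1)) {
  structure(list(domain = d, lams = lams,
                 provenance = list(oracle_id = oracle_id,
                                   u_global = u_global,
                                   build_params = build_params,
                                   log = character())),
            class = "lam_set")
}

#' @export
print.lam_set <- function(x, ...) {
  cat(sprintf("LAM set: %d model(s) over a %d-dimensional domain (oracle %s)\n",
              length(x$lams), domain_dim(x$domain), x$provenance$oracle_id))
  invisible(x)
}

#' @export
length.lam_set <- function(x) length(x$lams)

# matrix of reference conformations, one LAM per row
lamset_refs <- function(ls) {
  if (!length(ls$lams))
    return(matrix(numeric(), 0, domain_dim(ls$domain)))
  do.call(rbind, lapply(ls$lams, `[[`, "theta_ref"))
}

#' Add one LAM to a set
#'
#' Enforces the duplicate-spacing invariant: no two models may sit
#' closer than `eps_dup` under the conformational metric.
#'
#' @param ls a [lam_set()].
#' @param lam a [build_lam()] object.
#' @param eps_dup duplicate threshold in degrees (default 0.5).
#' @return the augmented `lam_set`.
#' @export
add_lam <- function(ls, lam, eps_dup = 0.5) {
  if (length(ls$lams)) {
    dd <- dist_to_rows(lamset_refs(ls), lam$theta_ref, ls$domain)
    if (any(dd < eps_dup))
      stop(sprintf("a LAM already exists within %g degrees of (%s)",
                   eps_dup, paste(signif(lam$theta_ref, 6), collapse = ", ")))
  }
  ls$lams[[length(ls$lams) + 1L]] <- lam
  ls
}

#' Build LAMs on a regular grid
#'
#' Constructs one LAM at every [regular_grid()] point of the domain.
#' `u_global` is located once per (oracle, domain) pair and shared by
#' all models.
#'
#' @inheritParams build_lam
#' @param convention grid convention, `"centered"` or `"nodes"`.
#' @param u_global optional precomputed global-minimum energy; when
#'   `NULL` it is found with [global_minimum()].
#' @param n_starts,seed passed to [global_minimum()].
#' @return a [lam_set()].
#' @export
build_lam_grid <- function(spec, d, convention = c("centered", "nodes"),
                           fd_step = 1, u_global = NULL, n_starts = 50,
                           seed = 1) {
  convention <- match.arg(convention)
  if (is.null(u_global))
    u_global <- global_minimum(spec, d, n_starts = n_starts,
                               seed = seed)$u_global
  g <- regular_grid(d, convention)
  ls <- lam_set(d, oracle_id = spec$id, u_global = u_global,
                build_params = list(fd_step = fd_step,
                                    grid_convention = convention))
  for (r in seq_len(nrow(g)))
    ls <- add_lam(ls, build_lam(spec, g[r, ], d, u_global, fd_step))
  ls$provenance$log <- sprintf("built %d LAMs on a %s grid", nrow(g),
                               convention)
  ls
}

#' Nearest LAM to a conformation
#'
#' The model whose reference conformation minimizes the
#' [torsion_distance()] to `theta`; exact ties are broken by the lowest
#' insertion index, so lookup is deterministic.
#'
#' @param ls a non-empty [lam_set()].
#' @param theta canonical torsion vector (degrees).
#' @param index return the index instead of the model object?
#' @return a `lam`, or its integer index when `index = TRUE`.
#' @export
nearest_lam <- function(ls, theta, index = FALSE) {
  if (!length(ls$lams)) stop("the LAM set is empty")
  dd <- dist_to_rows(lamset_refs(ls), check_dim(theta, ls$domain),
                     ls$domain)
  i <- which.min(dd)                   # which.min takes the first tie
  if (index) i else ls$lams[[i]]
}

#' Evaluate a LAM set at a conformation
#'
#' Nearest-model lookup followed by [evaluate_lam()]. The piecewise
#' surface is generally discontinuous across the midline between two
#' models that disagree there; no smoothing is applied.
#'
#' @inheritParams nearest_lam
#' @return list with `energy` (kJ/mol), `beta`, and `nearest` (model
#'   index).
#' @export
lamset_evaluate <- function(ls, theta) {
  i <- nearest_lam(ls, theta, index = TRUE)
  out <- evaluate_lam(ls$lams[[i]], theta, ls$domain)
  out$nearest <- i
  out
}

# vectorized energy prediction over a matrix of conformations;
# returns list(energy, nearest)
lamset_predict <- function(ls, thetas) {
  refs <- lamset_refs(ls)
  m <- nrow(thetas); k <- nrow(refs)
  best_d <- rep(Inf, m); nearest <- integer(m)
  for (j in seq_len(k)) {
    dj <- rowSums(angle_delta(refs[j, ], thetas, ls$domain)^2)
    upd <- dj < best_d
    best_d[upd] <- dj[upd]; nearest[upd] <- j
  }
  energy <- numeric(m)
  for (j in unique(nearest)) {
    rows <- which(nearest == j)
    lam <- ls$lams[[j]]
    delta <- angle_delta(lam$theta_ref, thetas[rows, , drop = FALSE],
                         ls$domain)
    energy[rows] <- lam$e_ref + delta %*% lam$b +
      0.5 * rowSums((delta %*% lam$A) * delta)
  }
  list(energy = energy, nearest = nearest)
}
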