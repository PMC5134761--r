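# Independent brute-force reference implementation of the adaptive
# sweep, written directly from the placement rules with its own angle
# arithmetic. It deliberately shares no geometry or decision code with
# the package; only the oracle build of an accepted midpoint goes
# through build_lam(), since both routes must add models with identical
# content for the logs to stay comparable.

ref_delta1 <- function(from, to, periodic) {
  d <- to - from
  if (periodic) d <- (d + 180) %% 360 - 180
  d
}

ref_delta <- function(from, to, dom)
  mapply(ref_delta1, from, to, dom$periodic)

ref_dist <- function(a, b, dom) sqrt(sum(ref_delta(a, b, dom)^2))

ref_canon <- function(theta, dom) {
  for (i in seq_along(theta)) if (dom$periodic[i]) {
    while (theta[i] < dom$lower[i]) theta[i] <- theta[i] + 360
    while (theta[i] >= dom$upper[i]) theta[i] <- theta[i] - 360
  }
  theta
}

ref_mid <- function(a, b, dom) {
  d <- ref_delta(a, b, dom)
  if (any(dom$periodic & abs(abs(d) - 180) < 1e-9)) return(NULL)
  ref_canon(a + d / 2, dom)
}

ref_eval <- function(lam, theta, dom) {
  d <- ref_delta(lam$theta_ref, theta, dom)
  lam$e_ref + sum(lam$b * d) + 0.5 * as.numeric(t(d) %*% lam$A %*% d)
}

# one decision, mirroring the documented rule set; `near_cand` are the
# indices eligible for the nearer-model veto, `dup_cand` for the
# duplicate veto
ref_decide <- function(lams, a, b, dom, p, near_cand, dup_cand) {
  rec <- list(pair_a = a, pair_b = b, midpoint = NA_character_,
              discrepancy = NA_real_, min_pred_energy = NA_real_,
              outcome = "rejected", blocking_criterion = NA_character_)
  M <- ref_mid(lams[[a]]$theta_ref, lams[[b]]$theta_ref, dom)
  if (is.null(M)) { rec$blocking_criterion <- "antipodal"; return(rec) }
  rec$midpoint <- paste(sprintf("%.10g", M), collapse = ";")
  r_ab <- ref_dist(lams[[a]]$theta_ref, M, dom)
  for (k in setdiff(near_cand, c(a, b)))
    if (ref_dist(lams[[k]]$theta_ref, M, dom) < r_ab - 1e-12) {
      rec$blocking_criterion <- "nearer_lam"; return(rec)
    }
  for (k in setdiff(dup_cand, c(a, b)))
    if (ref_dist(lams[[k]]$theta_ref, M, dom) < p$eps_dup) {
      rec$blocking_criterion <- "duplicate"; return(rec)
    }
  ea <- ref_eval(lams[[a]], M, dom)
  eb <- ref_eval(lams[[b]], M, dom)
  rec$discrepancy <- abs(ea - eb)
  rec$min_pred_energy <- min(ea, eb)
  if (rec$min_pred_energy > p$cutoff) rec$blocking_criterion <- "cutoff"
  else if (rec$discrepancy <= p$delta_e)
    rec$blocking_criterion <- "discrepancy"
  else rec$outcome <- "accepted"
  rec
}

ref_adapt <- function(ls, spec, p) {
  dom <- ls$domain
  lams <- ls$lams
  u <- ls$provenance$u_global
  decisions <- list()
  sweep_no <- 0L
  repeat {
    sweep_no <- sweep_no + 1L
    n0 <- length(lams)
    accepted <- FALSE
    for (a in seq_len(max(n0 - 1L, 0L))) for (b in seq(a + 1L, n0)) {
      near_cand <- if (p$mode == "single_pass") seq_len(n0)
                   else seq_along(lams)
      rec <- ref_decide(lams, a, b, dom, p, near_cand, seq_along(lams))
      rec$sweep <- sweep_no
      decisions[[length(decisions) + 1L]] <- rec
      if (rec$outcome == "accepted") {
        M <- as.numeric(strsplit(rec$midpoint, ";")[[1]])
        lams[[length(lams) + 1L]] <- build_lam(spec, M, dom, u,
                                               fd_step = 1)
        accepted <- TRUE
      }
    }
    if (p$mode == "single_pass" || !accepted) break
  }
  list(decisions = do.call(rbind, lapply(decisions, as.data.frame)),
       refs = do.call(rbind, lapply(lams, `[[`, "theta_ref")))
}

# compare a package decision log with the reference log
expect_same_decisions <- function(dec, ref_dec) {
  expect_equal(nrow(dec), nrow(ref_dec))
  expect_identical(dec$pair_a, ref_dec$pair_a)
  expect_identical(dec$pair_b, ref_dec$pair_b)
  expect_identical(dec$outcome, ref_dec$outcome)
  expect_identical(dec$blocking_criterion, ref_dec$blocking_criterion)
  expect_equal(dec$discrepancy, ref_dec$discrepancy, tolerance = 1e-9)
  expect_equal(dec$min_pred_energy, ref_dec$min_pred_energy,
               tolerance = 1e-9)
}

# post-hoc convergence audit: in `ls`, no pair may satisfy the
# relevance and nearer-model criteria yet disagree at its midpoint by
# more than delta_e
posthoc_max_discrepancy <- function(ls, p = adapt_params()) {
  n <- length(ls$lams)
  worst <- 0
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    rec <- check_pair(ls, a, b, p)
    passes_10_11 <- rec$outcome == "accepted" ||
      identical(rec$blocking_criterion, "discrepancy")
    if (passes_10_11) worst <- max(worst, rec$discrepancy)
  }
  worst
}

# lazily computed shared fixtures (built once per test run)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

coupled_fixture <- function() cached("coupled", {
  spec <- preset_potential("coupled_2d")
  d <- preset_domain("coupled_2d")
  gm <- global_minimum(spec, d, n_starts = 100, seed = 1)
  init <- build_lam_grid(spec, d, "centered", u_global = gm$u_global)
  res <- adapt_lams(init, spec,
                    adapt_params(mode = "iterate", max_new_lams = 2000))
  list(spec = spec, domain = d, u_global = gm$u_global, initial = init,
       result = res)
})

manual_lam <- function(theta_ref, e_ref, b, A, beta_ref = numeric(),
                       C = matrix(0, 0, length(theta_ref))) {
  structure(list(theta_ref = theta_ref, e_ref = e_ref, b = b,
                 A = if (is.matrix(A)) A else diag(A, length(theta_ref)),
                 beta_ref = beta_ref, C = C, payload = list()),
            class = "lam")
}
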