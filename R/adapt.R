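#' Parameters of the adaptive placement algorithm
#'
#' @param delta_e discrepancy threshold \eqn{\delta_E^{LAM}} in kJ/mol:
#'   a midpoint qualifies only if the two models' predictions there
#'   differ by strictly more than this (default 1).
#' @param cutoff relevance threshold \eqn{\Delta E^{cutoff}} in kJ/mol:
#'   a midpoint whose lower predicted energy exceeds this is outside the
#'   region that matters for the crystal search and is skipped
#'   (default 20).
#' @param mode `"single_pass"` sweeps the pairs of the initial set once;
#'   `"iterate"` repeats full sweeps, with newly added models joining
#'   later sweeps, until a sweep accepts nothing.
#' @param max_new_lams safety budget on additions; hitting it flags the
#'   result as non-converged.
#' @param pair_scope `"all"` considers every pair; `"within_radius"`
#'   skips pairs farther apart than `radius` (a performance guard --
#'   distant pairs are vetoed by the nearer-model criterion anyway).
#' @param radius pair-distance cap in degrees for
#'   `pair_scope = "within_radius"`.
#' @param eps_dup duplicate spacing threshold in degrees; also
#'   guarantees termination of iterate mode (only finitely many points
#'   at least `eps_dup` apart fit in the compact domain).
#' @return a list of class `adapt_params`.
#' @export
adapt_params <- function(delta_e = 1, cutoff = 20,
                         mode = c("single_pass", "iterate"),
                         max_new_lams = 1000L,
                         pair_scope = c("all", "within_radius"),
                         radius = Inf, eps_dup = 0.5) {
  stopifnot(delta_e > 0, cutoff > 0, max_new_lams >= 1, eps_dup > 0)
  structure(list(delta_e = delta_e, cutoff = cutoff,
                 mode = match.arg(mode),
                 max_new_lams = as.integer(max_new_lams),
                 pair_scope = match.arg(pair_scope), radius = radius,
                 eps_dup = eps_dup),
            class = "adapt_params")
}

empty_decisions <- function() {
  data.frame(sweep = integer(), pair_a = integer(), pair_b = integer(),
             midpoint = character(), discrepancy = numeric(),
             min_pred_energy = numeric(), outcome = character(),
             blocking_criterion = character(), stringsAsFactors = FALSE)
}

fmt_theta <- function(theta) paste(sprintf("%.10g", theta), collapse = ";")

# Decide one pair (a, b). `cand` are the indices eligible as "nearer
# third model" / duplicate candidates. Cheap geometric vetoes run
# before the energy criteria; acceptance requires all criteria, so the
# order only affects which blocker is reported (and is fixed, making
# decision logs deterministic).
decide_pair <- function(ls, a, b, p, cand, refs) {
  d <- ls$domain
  ta <- ls$lams[[a]]$theta_ref; tb <- ls$lams[[b]]$theta_ref
  rec <- list(pair_a = a, pair_b = b, midpoint = NA_character_,
              discrepancy = NA_real_, min_pred_energy = NA_real_,
              outcome = "rejected", blocking_criterion = NA_character_)
  M <- tryCatch(torsion_midpoint(ta, tb, d),
                lamadapt_antipodal = function(e) NULL)
  if (is.null(M)) {
    rec$blocking_criterion <- "antipodal"
    return(rec)
  }
  rec$midpoint <- fmt_theta(M)
  others <- setdiff(cand, c(a, b))
  r_ab <- torsion_distance(ta, M, d)
  if (length(others)) {
    dk <- dist_to_rows(refs[others, , drop = FALSE], M, d)
    if (any(dk < r_ab - 1e-12)) {
      rec$blocking_criterion <- "nearer_lam"
      return(rec)
    }
    if (any(dk < p$eps_dup)) {
      rec$blocking_criterion <- "duplicate"
      return(rec)
    }
  }
  ea <- evaluate_lam(ls$lams[[a]], M, d)$energy
  eb <- evaluate_lam(ls$lams[[b]], M, d)$energy
  rec$discrepancy <- abs(ea - eb)
  rec$min_pred_energy <- min(ea, eb)
  if (rec$min_pred_energy > p$cutoff) {
    rec$blocking_criterion <- "cutoff"
  } else if (rec$discrepancy <= p$delta_e) {
    rec$blocking_criterion <- "discrepancy"
  } else {
    rec$outcome <- "accepted"
  }
  rec
}

#' Test the placement criteria for one pair of LAMs
#'
#' Evaluates the midpoint-discrepancy placement rule for models `a` and
#' `b` of the set: the midpoint `M` of their reference conformations is
#' accepted for a new model only if (i) the two predictions of
#' `deltaE_intra` at `M` differ by strictly more than `delta_e`, (ii)
#' the lower of the two predictions does not exceed `cutoff`, and (iii)
#' no third model of the set is strictly nearer to `M` than `a` and `b`
#' are (models exactly as near do not block). Antipodal periodic pairs
#' and midpoints duplicating an existing model within `eps_dup` are
#' rejected outright.
#'
#' @param ls a [lam_set()].
#' @param a,b distinct model indices.
#' @param p an [adapt_params()].
#' @return one-row data frame: `pair_a`, `pair_b`, `midpoint`
#'   (semicolon-joined degrees), `discrepancy`, `min_pred_energy`,
#'   `outcome` (`"accepted"`/`"rejected"`) and `blocking_criterion`
#'   (`NA`, `"discrepancy"`, `"cutoff"`, `"nearer_lam"`, `"antipodal"`
#'   or `"duplicate"`).
#' @export
check_pair <- function(ls, a, b, p = adapt_params()) {
  if (a == b) stop("a and b must be distinct models")
  rec <- decide_pair(ls, a, b, p, seq_along(ls$lams), lamset_refs(ls))
  cbind(data.frame(sweep = 1L), as.data.frame(rec, stringsAsFactors = FALSE))
}

#' Adaptive LAM placement
#'
#' Refines a LAM set by inserting models where neighbouring models
#' disagree. All unordered pairs are visited in lexicographic order of
#' their insertion indices; every accepted midpoint triggers a fresh
#' oracle build there ([build_lam()]).
#'
#' In `single_pass` mode only pairs of the *initial* set are considered
#' and decisions are made against the initial set, except that the
#' duplicate veto also consults models added earlier in the same pass
#' (on a regular grid two pairs can share a midpoint; the first
#' acceptance wins and later copies are logged as duplicates). In
#' `iterate` mode full sweeps over the current set are repeated -- new
#' models participate in later sweeps (and immediately in the
#' nearer-model and duplicate vetoes) -- until a sweep accepts nothing
#' or the budget is exhausted.
#'
#' @param ls a non-empty [lam_set()].
#' @param spec the [potential_spec()] oracle consistent with the set's
#'   provenance.
#' @param p an [adapt_params()].
#' @param fd_step finite-difference step for newly built models; by
#'   default taken from the set's build parameters.
#' @return list with `lamset` (augmented), `decisions` (the full log,
#'   one row per pair considered), `added`, `converged` and `sweeps`.
#' @export
adapt_lams <- function(ls, spec, p = adapt_params(), fd_step = NULL) {
  if (!length(ls$lams)) stop("the LAM set is empty")
  if (is.null(fd_step))
    fd_step <- ls$provenance$build_params$fd_step %||% 1
  u_global <- ls$provenance$u_global
  decisions <- list()
  added <- 0L
  converged <- TRUE
  sweep_no <- 0L
  repeat {
    sweep_no <- sweep_no + 1L
    n_sweep <- length(ls$lams)
    initial_only <- p$mode == "single_pass"
    pair_cand <- if (initial_only) seq_len(n_sweep) else NULL
    accepted_any <- FALSE
    for (a in seq_len(n_sweep - 1L)) {
      for (b in seq((a + 1L), n_sweep)) {
        if (is.finite(p$radius) && p$pair_scope == "within_radius" &&
            torsion_distance(ls$lams[[a]]$theta_ref,
                             ls$lams[[b]]$theta_ref, ls$domain) > p$radius)
          next
        refs <- lamset_refs(ls)
        # in single-pass mode, same-pass additions enter only the
        # duplicate veto, not the nearer-model criterion
        rec <- if (initial_only)
          decide_single_pass(ls, a, b, p, pair_cand, refs, n_sweep)
        else decide_pair(ls, a, b, p, seq_along(ls$lams), refs)
        rec$sweep <- sweep_no
        decisions[[length(decisions) + 1L]] <- rec
        if (identical(rec$outcome, "accepted")) {
          M <- as.numeric(strsplit(rec$midpoint, ";")[[1]])
          ls <- add_lam(ls, build_lam(spec, M, ls$domain, u_global,
                                      fd_step),
                        eps_dup = p$eps_dup)
          added <- added + 1L
          accepted_any <- TRUE
          if (added >= p$max_new_lams) {
            converged <- FALSE
            warning("max_new_lams budget exhausted; result is partial")
            break
          }
        }
      }
      if (!converged) break
    }
    if (p$mode == "single_pass" || !accepted_any || !converged) break
  }
  dec <- do.call(rbind, lapply(decisions, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(dec)) dec <- empty_decisions()
  dec <- dec[, c("sweep", "pair_a", "pair_b", "midpoint", "discrepancy",
                 "min_pred_energy", "outcome", "blocking_criterion")]
  ls$provenance$log <- c(ls$provenance$log,
                         sprintf("adapt (%s): %d added in %d sweep(s)",
                                 p$mode, added, sweep_no))
  list(lamset = ls, decisions = dec, added = added,
       converged = converged, sweeps = sweep_no)
}

# single-pass decision: nearer-model candidates are the initial set
# only, while the duplicate veto also sees same-pass additions
decide_single_pass <- function(ls, a, b, p, initial, refs, n_initial) {
  d <- ls$domain
  ta <- ls$lams[[a]]$theta_ref; tb <- ls$lams[[b]]$theta_ref
  rec <- list(pair_a = a, pair_b = b, midpoint = NA_character_,
              discrepancy = NA_real_, min_pred_energy = NA_real_,
              outcome = "rejected", blocking_criterion = NA_character_)
  M <- tryCatch(torsion_midpoint(ta, tb, d),
                lamadapt_antipodal = function(e) NULL)
  if (is.null(M)) { rec$blocking_criterion <- "antipodal"; return(rec) }
  rec$midpoint <- fmt_theta(M)
  dk_all <- dist_to_rows(refs, M, d)
  near_cand <- setdiff(initial, c(a, b))
  r_ab <- torsion_distance(ta, M, d)
  if (length(near_cand) && any(dk_all[near_cand] < r_ab - 1e-12)) {
    rec$blocking_criterion <- "nearer_lam"; return(rec)
  }
  dup_cand <- setdiff(seq_along(ls$lams), c(a, b))
  if (length(dup_cand) && any(dk_all[dup_cand] < p$eps_dup)) {
    rec$blocking_criterion <- "duplicate"; return(rec)
  }
  ea <- evaluate_lam(ls$lams[[a]], M, d)$energy
  eb <- evaluate_lam(ls$lams[[b]], M, d)$energy
  rec$discrepancy <- abs(ea - eb)
  rec$min_pred_energy <- min(ea, eb)
  if (rec$min_pred_energy > p$cutoff) {
    rec$blocking_criterion <- "cutoff"
  } else if (rec$discrepancy <= p$delta_e) {
    rec$blocking_criterion <- "discrepancy"
  } else rec$outcome <- "accepted"
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Edge-energy domain expansion
#'
#' Checks the relaxed intramolecular energy at the edges of every
#' non-periodic dimension (other coordinates held at the domain centre)
#' and, while an edge energy lies below `threshold`, extends that edge
#' outwards by `increment` -- the usual practice of widening a crystal
#' structure prediction search domain until the conformations at its
#' boundary are too strained to matter. Periodic dimensions already
#' cover the full circle and are left untouched. A dimension whose span
#' reaches `max_span` is capped with a warning.
#'
#' @param spec a [potential_spec()].
#' @param d the starting [torsion_domain()].
#' @param threshold edge-energy threshold in kJ/mol (default 15).
#' @param increment extension step in degrees.
#' @param max_span span cap in degrees (default 360).
#' @param u_global optional precomputed global-minimum reference; found
#'   with [global_minimum()] on the *starting* domain when `NULL`.
#' @return the expanded [torsion_domain()], with an `expansion_log`
#'   attribute listing the per-edge energy trajectories.
#' @export
expand_domain <- function(spec, d, threshold = 15, increment = 30,
                          max_span = 360, u_global = NULL) {
  stopifnot(increment > 0)
  if (is.null(u_global)) u_global <- global_minimum(spec, d)$u_global
  log <- list()
  centre <- function(dd) (dd$lower + dd$upper) / 2
  for (i in seq_along(d$lower)) {
    if (d$periodic[i]) {
      log[[d$names[i]]] <- "periodic: full circle, not expanded"
      next
    }
    for (edge in c("lower", "upper")) {
      traj <- numeric()
      repeat {
        theta <- centre(d)
        theta[i] <- d[[edge]][i]
        e <- relaxed_energy(spec, theta) - u_global
        traj <- c(traj, e)
        span <- d$upper[i] - d$lower[i]
        if (e >= threshold) break
        if (span >= max_span - 1e-9) {
          warning(sprintf(
            "dimension %s reached the %g-degree span cap while its %s edge energy is %.3g kJ/mol",
            d$names[i], max_span, edge, e))
          break
        }
        step <- min(increment, max_span - span)
        if (edge == "lower") d$lower[i] <- d$lower[i] - step
        else d$upper[i] <- d$upper[i] + step
      }
      log[[paste(d$names[i], edge, sep = ".")]] <- traj
    }
  }
  attr(d, "expansion_log") <- log
  d
}
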