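test_that("the placement criteria decide hand-built pairs correctly", {
  d <- torsion_domain(-90, 90, half_spacing = 30)
  base <- list(manual_lam(0, 0, 0, 0.01), manual_lam(60, 10, 0, 0.01))
  p <- adapt_params(delta_e = 1, cutoff = 20)
  # predictions at the midpoint 30: 4.5 vs 14.5 -> accepted
  dec <- check_pair(lam_set(d, base), 1, 2, p)
  expect_identical(dec$outcome, "accepted")
  expect_equal(dec$discrepancy, 10)
  expect_equal(dec$min_pred_energy, 4.5)
  # a third model sitting at the midpoint vetoes the pair
  with_third <- lam_set(d, c(base, list(manual_lam(30, 5, 0, 0.01))))
  dec2 <- check_pair(with_third, 1, 2, p)
  expect_identical(dec2$blocking_criterion, "nearer_lam")
  # shifting both predictions by +20 pushes the lower one past the cutoff
  shifted <- lam_set(d, list(manual_lam(0, 20, 0, 0.01),
                             manual_lam(60, 30, 0, 0.01)))
  dec3 <- check_pair(shifted, 1, 2, p)
  expect_identical(dec3$blocking_criterion, "cutoff")
  expect_equal(dec3$min_pred_energy, 24.5)
  # equal models disagree by 0 -> discrepancy veto
  same <- lam_set(d, list(manual_lam(0, 0, 0, 0.01),
                          manual_lam(60, 0.9, 0, 0.01)))
  dec4 <- check_pair(same, 1, 2, p)
  expect_identical(dec4$blocking_criterion, "discrepancy")
  expect_error(check_pair(same, 2, 2, p), "distinct")
  # antipodal periodic pair is skipped
  circ <- torsion_domain(0, 360, TRUE, 30)
  anti <- lam_set(circ, list(manual_lam(0, 0, 0, 0.01),
                             manual_lam(180, 0, 0, 0.01)))
  expect_identical(check_pair(anti, 1, 2, p)$blocking_criterion,
                   "antipodal")
})

test_that("adaptation is a no-op on an exactly quadratic surface", {
  q <- preset_potential("quadratic")
  d <- preset_domain("quadratic")
  ls <- build_lam_grid(q, d, "centered", u_global = 0)
  for (mode in c("single_pass", "iterate")) {
    res <- adapt_lams(ls, q, adapt_params(mode = mode))
    expect_identical(res$added, 0L)
    expect_true(all(res$decisions$outcome == "rejected"))
    expect_true(res$converged)
  }
})

test_that("the double-well re-enactment inserts exactly the two midpoints", {
  dw <- preset_potential("double_well_1d")
  d <- preset_domain("double_well_1d")
  ls <- build_lam_grid(dw, d, "nodes", u_global = -5)
  expect_equal(vapply(ls$lams, function(l) l$theta_ref, 0),
               c(-90, -30, 30, 90))
  for (mode in c("single_pass", "iterate")) {
    res <- adapt_lams(ls, dw, adapt_params(mode = mode))
    expect_identical(res$added, 2L)
    expect_identical(length(res$lamset), 6L)
    new_refs <- sort(vapply(res$lamset$lams[5:6],
                            function(l) l$theta_ref, 0))
    expect_equal(new_refs, c(-60, 60), tolerance = 1e-9)
    # the symmetric boundary at 0 stays un-refined
    zero_dec <- res$decisions[res$decisions$midpoint == "0", ]
    expect_true(all(zero_dec$outcome == "rejected"))
  }
})

test_that("package decisions match the brute-force reference on seeded specs", {
  n_specs <- 0L
  for (seed in 1:12) {
    for (setup in list(
      list(nd = 1, dom = torsion_domain(-90, 90, FALSE, 30),
           conv = "nodes"),
      list(nd = 2, dom = torsion_domain(c(0, 0), c(360, 360), TRUE, 60),
           conv = "centered"))) {
      spec <- random_spec(seed, n_indep = setup$nd, n_dep = 1,
                          barrier_range = c(2, 12))
      u <- global_minimum(spec, setup$dom, n_starts = 30,
                          seed = seed)$u_global
      ls <- build_lam_grid(spec, setup$dom, setup$conv, u_global = u)
      mode <- if (seed %% 2) "single_pass" else "iterate"
      p <- adapt_params(mode = mode, max_new_lams = 200)
      res <- adapt_lams(ls, spec, p)
      ref <- ref_adapt(ls, spec, p)
      expect_same_decisions(res$decisions, ref$decisions)
      expect_equal(do.call(rbind, lapply(res$lamset$lams,
                                         `[[`, "theta_ref")),
                   ref$refs, tolerance = 1e-12,
                   ignore_attr = TRUE)
      n_specs <- n_specs + 1L
    }
  }
  expect_gte(n_specs, 20L)
})

test_that("tightening the discrepancy threshold never places fewer models", {
  spec <- random_spec(4, n_indep = 2, n_dep = 1, barrier_range = c(2, 12))
  d <- torsion_domain(c(0, 0), c(360, 360), TRUE, 60)
  u <- global_minimum(spec, d, n_starts = 30, seed = 4)$u_global
  ls <- build_lam_grid(spec, d, "centered", u_global = u)
  added <- vapply(c(4, 2, 1, 0.5, 0.25), function(delta)
    adapt_lams(ls, spec, adapt_params(delta_e = delta,
                                      mode = "single_pass"))$added, 0L)
  expect_true(all(diff(added) >= 0))
})

test_that("adaptation is deterministic and respects domain and budget bounds", {
  spec <- random_spec(10, n_indep = 2, n_dep = 1, barrier_range = c(2, 12))
  d <- torsion_domain(c(0, 0), c(360, 360), TRUE, 60)
  u <- global_minimum(spec, d, n_starts = 30, seed = 10)$u_global
  ls <- build_lam_grid(spec, d, "centered", u_global = u)
  r1 <- adapt_lams(ls, spec, adapt_params(mode = "single_pass"))
  r2 <- adapt_lams(ls, spec, adapt_params(mode = "single_pass"))
  expect_identical(r1$decisions, r2$decisions)
  # single-pass additions are bounded by the initial pair count
  n0 <- length(ls)
  expect_lte(r1$added, choose(n0, 2))
  refs <- do.call(rbind, lapply(r1$lamset$lams, `[[`, "theta_ref"))
  expect_true(all(refs >= 0 & refs < 360))
  # an exhausted budget is flagged
  expect_warning(
    rb <- adapt_lams(ls, spec, adapt_params(mode = "iterate",
                                            max_new_lams = 1)),
    "budget")
  expect_false(rb$converged)
  expect_identical(rb$added, 1L)
})

test_that("iterate mode converges: no remaining qualifying pair disagrees", {
  spec <- random_spec(6, n_indep = 1, n_dep = 1, barrier_range = c(2, 10))
  d <- torsion_domain(-90, 90, FALSE, 30)
  u <- global_minimum(spec, d, n_starts = 30, seed = 6)$u_global
  ls <- build_lam_grid(spec, d, "nodes", u_global = u)
  res <- adapt_lams(ls, spec, adapt_params(mode = "iterate"))
  expect_true(res$converged)
  expect_lte(posthoc_max_discrepancy(res$lamset), 1)
})

test_that("edge-energy expansion widens low-energy boundaries as predicted", {
  # steep well in the middle: both edges already strained -> no change
  steep <- potential_spec(1, quadratic = list(theta0 = 0, curvature = 0.05),
                          id = "steep")
  d <- torsion_domain(-60, 60, FALSE, 15)
  expect_equal(expand_domain(steep, d, threshold = 15, increment = 30,
                             u_global = 0)[c("lower", "upper")],
               d[c("lower", "upper")])
  # harmonic well centred on the upper edge: the closed-form crossing
  # sqrt(2 * 15 / 0.01) = 54.77 deg past the centre, reached within one
  # 30-degree increment
  well <- potential_spec(1, quadratic = list(theta0 = 90, curvature = 0.01),
                         id = "edge-well")
  d2 <- torsion_domain(0, 90, FALSE, 15)
  ex <- expand_domain(well, d2, threshold = 15, increment = 30,
                      u_global = 0)
  expect_equal(ex$upper, 150)       # 90 + 2 increments; 144.77 crossing
  expect_equal(ex$lower, 0)         # lower edge energy 40.5 > 15 already
  traj <- attr(ex, "expansion_log")$T1.upper
  expect_true(all(traj[-length(traj)] < 15) &&
                traj[length(traj)] >= 15)
  # periodic dimensions are never expanded
  circ <- torsion_domain(0, 360, TRUE, 30)
  flat <- potential_spec(1, fourier = data.frame(dim = 1, mult = 1,
                                                 barrier = 0.5, phase = 0),
                         id = "flat")
  ex2 <- expand_domain(flat, circ, u_global = 0)
  expect_equal(ex2$lower, 0); expect_equal(ex2$upper, 360)
  # a span cap on a too-flat dimension warns and returns the cap
  d3 <- torsion_domain(-30, 30, FALSE, 15)
  w <- capture_warnings(ex3 <- expand_domain(flat, d3, threshold = 15,
                                             increment = 30,
                                             max_span = 120,
                                             u_global = 0))
  expect_true(any(grepl("span cap", w)))
  expect_lte(ex3$upper - ex3$lower, 120)
})
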