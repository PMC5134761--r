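test_that("LAM construction recovers quadratic closed forms exactly", {
  q <- preset_potential("quadratic")
  d <- preset_domain("quadratic")
  l <- build_lam(q, 30, d, u_global = 0)
  expect_equal(l$e_ref, 0.5 * 0.01 * 30^2, tolerance = 1e-10)
  expect_equal(l$b, 0.01 * 30, tolerance = 1e-10)
  expect_equal(as.numeric(l$A), 0.01, tolerance = 1e-10)
  expect_equal(as.numeric(l$C), 0.1, tolerance = 1e-10)
  expect_equal(l$beta_ref, 3)                 # 0.1 * 30
})

test_that("finite-difference derivatives are step-consistent and match analytics", {
  dw <- preset_potential("double_well_1d")
  d <- preset_domain("double_well_1d")
  for (tr in c(-75, -10, 40)) {
    l_coarse <- build_lam(dw, tr, d, -5, fd_step = 0.5)
    l_fine <- build_lam(dw, tr, d, -5, fd_step = 0.25)
    # central differences converge as O(step^2): quartering the error
    g_true <- drop(lamadapt:::relaxed_gradient(dw, matrix(tr, 1)))
    err_coarse <- abs(l_coarse$b - g_true)
    err_fine <- abs(l_fine$b - g_true)
    expect_lt(err_fine, err_coarse / 3 + 1e-12)
    expect_equal(l_coarse$b, l_fine$b, tolerance = 1e-3)
    expect_equal(as.numeric(l_coarse$A), as.numeric(l_fine$A),
                 tolerance = 1e-3)
  }
  # gradient vanishes on the symmetric barrier top
  l0 <- build_lam(dw, 0, d, -5)
  expect_equal(l0$b, 0, tolerance = 1e-10)
  # cross second derivatives are symmetrized and match the coupling
  cp <- preset_potential("coupled_2d")
  l2 <- build_lam(cp, c(80, 60), preset_domain("coupled_2d"), -2)
  expect_identical(l2$A, t(l2$A))
})

test_that("LAM evaluation matches hand-computed second-order predictions", {
  d <- torsion_domain(-90, 90, half_spacing = 30)
  lam_a <- manual_lam(0, 0, 0, 0.01)
  lam_b <- manual_lam(60, 10, 0, 0.01)
  expect_equal(evaluate_lam(lam_a, 30, d)$energy, 4.5)
  expect_equal(evaluate_lam(lam_b, 30, d)$energy, 14.5)
  expect_equal(evaluate_lam(lam_a, 0, d)$energy, 0)
  # dependent coordinates follow the linear sensitivity model
  lam_c <- manual_lam(10, 1, 0.2, 0.05, beta_ref = c(1, -1),
                      C = matrix(c(0.1, -0.02), 2, 1))
  out <- evaluate_lam(lam_c, 30, d)
  expect_equal(out$beta, c(1 + 0.1 * 20, -1 - 0.02 * 20))
})

test_that("a single LAM reproduces a quadratic oracle over the whole domain", {
  q <- preset_potential("quadratic")
  d <- preset_domain("quadratic")
  ls <- lam_set(d, oracle_id = q$id, u_global = 0)
  ls <- add_lam(ls, build_lam(q, -75, d, 0))
  th <- seq(-90, 90, by = 1)
  pred <- vapply(th, function(x) lamset_evaluate(ls, x)$energy, 0)
  truth <- relaxed_energy(q, matrix(th, ncol = 1))
  expect_lt(max(abs(pred - truth)), 1e-8)
})

test_that("local model error shrinks with third-order scaling in the cell width", {
  dw <- preset_potential("double_well_1d")
  d <- preset_domain("double_well_1d")
  max_err <- function(tr, half) {
    l <- build_lam(dw, tr, d, -5)
    th <- seq(tr - half, tr + half, by = 0.25)
    pred <- vapply(th, function(x) evaluate_lam(l, x, d)$energy, 0)
    max(abs(pred - (relaxed_energy(dw, matrix(th, ncol = 1)) + 5)))
  }
  for (tr in c(-45, 15, 50)) {
    errs <- vapply(c(16, 8, 4), max_err, 0, tr = tr)
    expect_gte(errs[1] / errs[2], 3)
    expect_gte(errs[2] / errs[3], 3)
  }
})

test_that("nearest-model lookup agrees with exhaustive search and breaks ties low", {
  d <- torsion_domain(0, 360, periodic = TRUE, half_spacing = 30)
  mk <- function(tr) manual_lam(tr, 0, 0, 0)
  ls <- lam_set(d, list(mk(10), mk(350)))
  expect_identical(nearest_lam(ls, 355, index = TRUE), 2L)
  expect_identical(nearest_lam(ls, 2, index = TRUE), 1L)
  ls2 <- lam_set(torsion_domain(-90, 90, half_spacing = 30),
                 list(mk(0), mk(60)))
  expect_identical(nearest_lam(ls2, 29, index = TRUE), 1L)
  expect_identical(nearest_lam(ls2, 31, index = TRUE), 2L)
  expect_identical(nearest_lam(ls2, 30, index = TRUE), 1L)  # tie -> first
  set.seed(13)
  refs <- runif(12, 0, 360)
  ls3 <- lam_set(d, lapply(refs, mk))
  for (i in 1:30) {
    th <- runif(1, 0, 360)
    brute <- which.min(vapply(refs, torsion_distance, 0, b = th, d = d))
    expect_identical(nearest_lam(ls3, th, index = TRUE), brute)
  }
})

test_that("piecewise evaluation jumps by the midpoint discrepancy at the midline", {
  d <- torsion_domain(-90, 90, half_spacing = 30)
  ls <- lam_set(d, list(manual_lam(0, 0, 0, 0.01),
                        manual_lam(60, 10, 0, 0.01)))
  disc <- abs(evaluate_lam(ls$lams[[1]], 30, d)$energy -
                evaluate_lam(ls$lams[[2]], 30, d)$energy)
  eps <- 1e-9
  jump <- abs(lamset_evaluate(ls, 30 + eps)$energy -
                lamset_evaluate(ls, 30 - eps)$energy)
  expect_equal(jump, disc, tolerance = 1e-6)
})

test_that("LAM sets round-trip through JSON bit-identically", {
  cp <- preset_potential("coupled_2d")
  d <- preset_domain("coupled_2d")
  ls <- lam_set(d, oracle_id = cp$id, u_global = -1.5)
  for (tr in list(c(60, 60), c(180, 300.123456789)))
    ls <- add_lam(ls, build_lam(cp, tr, d, -1.5,
                                payload = list(level = "synthetic")))
  f <- withr::local_tempfile(fileext = ".json")
  write_lamset(ls, f)
  ls2 <- read_lamset(f)
  keep <- c("theta_ref", "e_ref", "b", "A", "beta_ref", "C")
  expect_identical(lapply(ls2$lams, `[`, keep), lapply(ls$lams, `[`, keep))
  expect_identical(ls2$provenance$u_global, ls$provenance$u_global)
  expect_equal(ls2$domain, ls$domain)
  expect_identical(ls2$lams[[1]]$payload$level, "synthetic")
})

test_that("schema violations are rejected and unknown fields are preserved", {
  d <- preset_domain("quadratic")
  q <- preset_potential("quadratic")
  ls <- lam_set(d, list(build_lam(q, 10, d, 0)), oracle_id = q$id)
  f <- withr::local_tempfile(fileext = ".json")
  write_lamset(ls, f)
  obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  # missing required field
  broken <- obj; broken$u_global <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(broken, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_lamset(f2), "u_global",
               class = "lamadapt_schema_error")
  # asymmetric curvature matrix in a 2-D file
  cp <- preset_potential("coupled_2d")
  dc <- preset_domain("coupled_2d")
  ls2 <- lam_set(dc, list(build_lam(cp, c(60, 60), dc, -1.5)),
                 oracle_id = cp$id, u_global = -1.5)
  f3 <- withr::local_tempfile(fileext = ".json")
  write_lamset(ls2, f3)
  obj2 <- jsonlite::fromJSON(f3, simplifyVector = FALSE)
  obj2$lams[[1]]$a[[2]] <- as.numeric(obj2$lams[[1]]$a[[2]]) + 1e-3
  f4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, f4, auto_unbox = TRUE, digits = NA)
  expect_error(read_lamset(f4), "not symmetric",
               class = "lamadapt_schema_error")
  # unknown extra fields are folded into the payload, with a message
  obj$lams[[1]]$point_charges <- list(0.1, -0.1)
  f5 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f5, auto_unbox = TRUE, digits = NA)
  expect_message(ls3 <- read_lamset(f5), "point_charges")
  expect_equal(unlist(ls3$lams[[1]]$payload$point_charges), c(0.1, -0.1))
})

test_that("reference energies below the global minimum are caught", {
  q <- preset_potential("quadratic")
  d <- preset_domain("quadratic")
  e0 <- relaxed_energy(q, 20)
  expect_warning(l <- build_lam(q, 20, d, u_global = e0 + 5e-7),
                 "clamping")
  expect_identical(l$e_ref, 0)
  expect_error(build_lam(q, 20, d, u_global = e0 + 1), "u_global is wrong")
  expect_error(build_lam(q, 120, d, u_global = 0), "outside the domain")
})

test_that("duplicate reference conformations cannot enter a set", {
  q <- preset_potential("quadratic")
  d <- preset_domain("quadratic")
  ls <- lam_set(d, list(build_lam(q, 10, d, 0)))
  expect_error(add_lam(ls, build_lam(q, 10.2, d, 0)), "already exists")
  expect_silent(add_lam(ls, build_lam(q, 11, d, 0)))
})
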