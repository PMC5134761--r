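#' Shipped potential presets
#'
#' Frozen synthetic surfaces used throughout the documentation, the test
#' suite and the demos:
#' \describe{
#'   \item{`quadratic`}{a pure quadratic well in one torsion,
#'     `E = 0.5 * 0.01 * theta^2` kJ/mol about `theta0 = 0` on the
#'     bounded domain `[-90, 90]`, with one dependent coordinate
#'     following `beta_hat(theta) = 0.1 * theta` at stiffness 1. A
#'     second-order model is exact on this surface, so any LAM set
#'     reproduces it to round-off and adaptive placement adds nothing.}
#'   \item{`double_well_1d`}{`E(theta) = 20 (1 - cos 2 theta)
#'     - 10 (1 - cos 4 theta)` on `[-90, 90]`: symmetric wells at
#'     +/-30 degrees, a 5 kJ/mol barrier at 0 and 45 kJ/mol walls at
#'     +/-90. With models seeded at -90, -30, +30 and +90 degrees the
#'     adjacent-model mismatch at +/-60 is 4.3 kJ/mol while symmetry
#'     makes the mismatch at 0 vanish, so adaptive placement inserts
#'     exactly two refinement models.}
#'   \item{`coupled_2d`}{a periodic two-torsion surface
#'     `250 (1 - cos(t1 - t2 - 20)) + 8 (1 - cos(t1 - 60))
#'     + 3 cos(6 t1 + 15) cos(6 t2 + 45)` whose low-energy region is a
#'     narrow diagonal band (the two torsions are strongly correlated,
#'     so the basins are not axis-aligned rectangles) carrying
#'     fine-scale corrugation; the diagonal wall is expressed through
#'     two product-coupling terms. Used by the adaptive-efficiency
#'     analyses and the `roy` demo.}
#' }
#'
#' @param name one of `"quadratic"`, `"double_well_1d"`, `"coupled_2d"`.
#' @return a [potential_spec()] (for [preset_potential()]) or a
#'   [torsion_domain()] (for [preset_domain()]).
#' @export
preset_potential <- function(name = c("quadratic", "double_well_1d",
                                      "coupled_2d")) {
  name <- match.arg(name)
  switch(name,
    quadratic = potential_spec(
      n_indep = 1, n_dep = 1,
      quadratic = list(theta0 = 0, curvature = 0.01),
      dep = list(list(beta0 = 0,
                      terms = data.frame(dim = 1, slope = 0.1,
                                         mult = 0, phase = 0))),
      kappa = 1, id = "preset:quadratic"),
    double_well_1d = potential_spec(
      n_indep = 1, n_dep = 1,
      fourier = data.frame(dim = c(1, 1), mult = c(2, 4),
                           barrier = c(20, -10), phase = c(0, 0)),
      dep = list(list(beta0 = 0.1,
                      terms = data.frame(dim = 1, slope = 0.3,
                                         mult = 1, phase = 30))),
      kappa = 2, id = "preset:double_well_1d"),
    coupled_2d = potential_spec(
      n_indep = 2, n_dep = 2,
      fourier = data.frame(dim = 1, mult = 1, barrier = 8, phase = -60),
      coupling = data.frame(
        dim_i = c(1, 1, 1), dim_j = c(2, 2, 2),
        amp = c(-250, -250, 3),
        mult_i = c(1, 1, 6), mult_j = c(1, 1, 6),
        phase_i = c(0, -90, 15), phase_j = c(20, -70, 45)),
      dep = list(
        list(beta0 = 0.2,
             terms = data.frame(dim = 1, slope = 0.4, mult = 1,
                                phase = 10)),
        list(beta0 = -0.1,
             terms = data.frame(dim = c(2, 1), slope = c(0.25, 0.15),
                                mult = c(2, 1), phase = c(-40, 70)))),
      kappa = c(1.5, 1), const = 250, id = "preset:coupled_2d"))
}

#' @rdname preset_potential
#' @export
preset_domain <- function(name = c("quadratic", "double_well_1d",
                                   "coupled_2d")) {
  name <- match.arg(name)
  switch(name,
    quadratic = torsion_domain(-90, 90, FALSE, 15, names = "T1"),
    double_well_1d = torsion_domain(-90, 90, FALSE, 30, names = "T1"),
    coupled_2d = torsion_domain(c(0, 0), c(360, 360), c(TRUE, TRUE),
                                c(60, 60), names = c("T1", "T2")))
}

#' Resolve an oracle identifier
#'
#' Maps the identifiers used by the command-line surface to potential
#' objects: `preset:<name>`, `random:<seed>`, or a path to a serialized
#' potential JSON file.
#'
#' @param id identifier string.
#' @param ... passed through to [random_spec()] for `random:<seed>`.
#' @return a [potential_spec()].
#' @export
resolve_oracle <- function(id, ...) {
  if (inherits(id, "potential_spec")) return(id)
  if (grepl("^preset:", id)) {
    name <- sub("^preset:", "", id)
    if (!name %in% c("quadratic", "double_well_1d", "coupled_2d"))
      stop("cannot resolve oracle identifier: unknown preset '", name, "'")
    return(preset_potential(name))
  }
  if (grepl("^random:", id)) {
    seed <- suppressWarnings(as.integer(sub("^random:", "", id)))
    if (is.na(seed)) stop("random oracle id must be 'random:<integer>'")
    return(random_spec(seed, ...))
  }
  if (file.exists(id)) return(read_potential(id))
  stop("cannot resolve oracle identifier: ", id)
}
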