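#' Torsional search domain
#'
#' Defines the hyper-rectangular search space of the independent torsion
#' angles: per-dimension lower and upper bounds (degrees), a periodicity
#' flag, and the LAM validity half-width `half_spacing` used to lay out
#' regular grids. A periodic dimension covers a full circle, so its span
#' must be exactly 360 degrees and angular arithmetic on it uses the
#' shorter arc.
#'
#' @param lower,upper numeric vectors of per-dimension bounds, in degrees.
#' @param periodic logical vector; `TRUE` marks a full-circle dimension.
#' @param half_spacing numeric vector of positive grid half-widths
#'   (degrees); a grid cell spans `2 * half_spacing`.
#' @param names optional character vector of dimension names (e.g.
#'   `"T1"`); defaults to `T1..Tn`.
#' @return An object of class `torsion_domain`.
#' @examples
#' torsion_domain(c(0, 95), c(360, 185), c(TRUE, FALSE), c(15, 15))
#' @export
torsion_domain <- function(lower, upper, periodic = FALSE,
                           half_spacing = 15, names = NULL) {
  n <- length(lower)
  periodic <- rep_len(as.logical(periodic), n)
  half_spacing <- rep_len(as.numeric(half_spacing), n)
  if (length(upper) != n)
    stop("lower and upper must have the same length")
  if (is.null(names)) names <- paste0("T", seq_len(n))
  if (any(bad <- !periodic & !(lower < upper)))
    stop("lower bound must be below upper bound for non-periodic dimension(s) ",
         paste(which(bad), collapse = ", "))
  if (any(bad <- periodic & abs((upper - lower) - 360) > 1e-9))
    stop("periodic dimension(s) ", paste(which(bad), collapse = ", "),
         " must span exactly 360 degrees")
  if (any(half_spacing <= 0))
    stop("half_spacing must be positive")
  structure(list(names = as.character(names), lower = as.numeric(lower),
                 upper = as.numeric(upper), periodic = periodic,
                 half_spacing = half_spacing),
            class = "torsion_domain")
}

#' @export
print.torsion_domain <- function(x, ...) {
  cat("Torsion domain with", domain_dim(x), "dimension(s):\n")
  for (i in seq_along(x$lower))
    cat(sprintf("  %s: [%g, %g%s), half-spacing %g deg\n", x$names[i],
                x$lower[i], x$upper[i],
                if (x$periodic[i]) ", periodic" else "", x$half_spacing[i]))
  invisible(x)
}

#' Number of dimensions of a torsion domain
#' @param d a [torsion_domain()].
#' @return integer dimension count.
#' @export
domain_dim <- function(d) length(d$lower)

check_dim <- function(theta, d, what = "theta") {
  theta <- as.numeric(theta)
  if (length(theta) != domain_dim(d))
    stop(sprintf("%s has length %d but the domain has %d dimension(s)",
                 what, length(theta), domain_dim(d)))
  theta
}

#' Canonicalize a torsion vector
#'
#' Wraps every periodic coordinate into `[lower, lower + 360)`;
#' non-periodic coordinates are returned unchanged. Idempotent.
#'
#' @param theta numeric vector of torsion angles (degrees).
#' @param d a [torsion_domain()].
#' @return numeric vector of the same length, canonical in `d`.
#' @export
canonicalize <- function(theta, d) {
  theta <- check_dim(theta, d)
  p <- d$periodic
  theta[p] <- d$lower[p] + ((theta[p] - d$lower[p]) %% 360 + 360) %% 360
  # guard against -1e-16 %% 360 == 360
  theta[p & theta >= d$upper] <- d$lower[p & theta >= d$upper]
  theta
}

# Signed per-dimension difference `to - from` in degrees. Periodic
# dimensions report the shorter arc, in [-180, 180). `from` may be a
# vector and `to` a matrix with one point per row (or vice versa).
angle_delta <- function(from, to, d) {
  delta <- if (is.matrix(to)) sweep(to, 2, from) else to - from
  p <- d$periodic
  if (any(p)) {
    if (is.matrix(delta)) {
      delta[, p] <- (delta[, p, drop = FALSE] + 180) %% 360 - 180
    } else {
      delta[p] <- (delta[p] + 180) %% 360 - 180
    }
  }
  delta
}

#' Conformational distance between two torsion vectors
#'
#' Euclidean norm of the per-dimension angular differences, where each
#' periodic dimension contributes its shorter-arc difference (at most
#' 180 degrees). This is the metric used by nearest-LAM lookup and by
#' the adaptive placement criteria.
#'
#' @param a,b canonical torsion vectors (degrees).
#' @param d a [torsion_domain()].
#' @return distance in degrees.
#' @examples
#' d <- torsion_domain(0, 360, periodic = TRUE)
#' torsion_distance(350, 10, d)  # 20, via the shorter arc
#' @export
torsion_distance <- function(a, b, d) {
  a <- check_dim(a, d, "a"); b <- check_dim(b, d, "b")
  sqrt(sum(angle_delta(a, b, d)^2))
}

# distances from one point to each row of a reference matrix
dist_to_rows <- function(refs, theta, d) {
  sqrt(rowSums(angle_delta(theta, refs, d)^2))
}

#' Midpoint of two torsion vectors
#'
#' Per-dimension midpoint along the shorter arc for periodic dimensions
#' and the arithmetic mean otherwise; the result is canonical and
#' equidistant from both arguments under [torsion_distance()]. For a
#' periodic dimension whose shorter-arc difference is 180 degrees
#' (within 1e-9) the midpoint is ambiguous and an error of class
#' `lamadapt_antipodal` is signalled; callers enumerating pairs should
#' skip such pairs.
#'
#' @inheritParams torsion_distance
#' @return canonical torsion vector (degrees).
#' @export
torsion_midpoint <- function(a, b, d) {
  a <- check_dim(a, d, "a"); b <- check_dim(b, d, "b")
  delta <- angle_delta(a, b, d)
  if (any(d$periodic & abs(abs(delta) - 180) < 1e-9))
    stop(structure(class = c("lamadapt_antipodal", "error", "condition"),
                   list(message = paste(
                     "periodic coordinates are antipodal; the midpoint is",
                     "ambiguous -- skip this pair"), call = sys.call(-1))))
  canonicalize(a + delta / 2, d)
}

#' Regular LAM grid over a torsion domain
#'
#' Cartesian product of per-dimension one-dimensional grids with spacing
#' `2 * half_spacing`. Two layout conventions are supported:
#' \describe{
#'   \item{`"centered"`}{cell-centre points at `lower + half_spacing`,
#'     `lower + 3 half_spacing`, ...; `span / (2 half_spacing)` points
#'     per dimension.}
#'   \item{`"nodes"`}{cell-corner points at `lower`, `lower + 2
#'     half_spacing`, ..., `upper`; one extra point per non-periodic
#'     dimension, while on a periodic dimension the endpoint coincides
#'     with the start and is dropped.}
#' }
#' Points are ordered lexicographically by dimension then value.
#'
#' @param d a [torsion_domain()]; `2 * half_spacing` must divide each
#'   span exactly (within 1e-9 degrees).
#' @param convention `"centered"` (default) or `"nodes"`.
#' @return numeric matrix, one canonical grid point per row.
#' @examples
#' d <- torsion_domain(-90, 90, half_spacing = 15)
#' nrow(regular_grid(d, "nodes"))  # 7 points: -90, -60, ..., 90
#' @export
regular_grid <- function(d, convention = c("centered", "nodes")) {
  convention <- match.arg(convention)
  span <- d$upper - d$lower
  cells <- span / (2 * d$half_spacing)
  if (any(abs(cells - round(cells)) > 1e-9))
    stop("2 * half_spacing must divide the span exactly for dimension(s) ",
         paste(which(abs(cells - round(cells)) > 1e-9), collapse = ", "))
  cells <- as.integer(round(cells))
  axes <- lapply(seq_along(cells), function(i) {
    h <- d$half_spacing[i]
    if (convention == "centered") {
      d$lower[i] + h + 2 * h * seq_len(cells[i]) - 2 * h
    } else if (d$periodic[i]) {
      d$lower[i] + 2 * h * (seq_len(cells[i]) - 1)
    } else {
      d$lower[i] + 2 * h * (seq_len(cells[i] + 1) - 1)
    }
  })
  # expand.grid varies the first factor fastest; feed axes reversed so
  # the first dimension varies slowest, giving lexicographic order
  g <- as.matrix(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
  dimnames(g) <- list(NULL, d$names)
  g
}

#' Read a torsion-domain configuration file
#'
#' Loads a YAML or JSON file holding a list of per-torsion entries
#' `{name, lower, upper, periodic, half_spacing}` (a top-level
#' `torsions:` key wrapping the list is also accepted) and validates it.
#'
#' @param path path to the config file; format is chosen by extension
#'   (`.json` vs anything else = YAML, which also parses JSON-like
#'   scalars).
#' @return a [torsion_domain()].
#' @export
read_domain_config <- function(path) {
  if (!file.exists(path)) stop("domain config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$torsions)) cfg <- cfg$torsions
  if (!length(cfg)) stop("domain config is empty: ", path)
  get_field <- function(entry, field, default = NULL) {
    v <- entry[[field]]
    if (is.null(v)) {
      if (is.null(default))
        stop(sprintf("domain config entry '%s' is missing field '%s'",
                     if (is.null(entry$name)) "?" else entry$name, field))
      v <- default
    }
    v
  }
  torsion_domain(
    lower = vapply(cfg, get_field, 0, field = "lower"),
    upper = vapply(cfg, get_field, 0, field = "upper"),
    periodic = vapply(cfg, function(e) isTRUE(e$periodic), FALSE),
    half_spacing = vapply(cfg, get_field, 0, field = "half_spacing"),
    names = vapply(cfg, function(e)
      as.character(get_field(e, "name", "T")), ""))
}

#' Write a torsion-domain configuration file
#' @param d a [torsion_domain()].
#' @param path output path (`.json` for JSON, otherwise YAML).
#' @return `path`, invisibly.
#' @export
write_domain_config <- function(d, path) {
  entries <- lapply(seq_along(d$lower), function(i)
    list(name = d$names[i], lower = d$lower[i], upper = d$upper[i],
         periodic = d$periodic[i], half_spacing = d$half_spacing[i]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(torsions = entries), path,
                         auto_unbox = TRUE, digits = I(17))
  } else {
    yaml::write_yaml(list(torsions = entries), path)
  }
  invisible(path)
}
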