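#' Dense-scan error map of a LAM set against its oracle
#'
#' Tabulates the LAM prediction, the oracle's relaxed energy and their
#' absolute difference over a node grid at `increment`-degree spacing,
#' optionally slicing the domain by holding some dimensions fixed --
#' the standard diagnostic for judging where a model library needs
#' refinement.
#'
#' @param ls a [lam_set()].
#' @param spec the [potential_spec()] oracle.
#' @param increment scan spacing in degrees; must divide the scanned
#'   spans exactly (within 1e-9).
#' @param fixed optional named numeric vector of dimension values to
#'   hold constant (names from the domain); the remaining dimensions
#'   are scanned.
#' @return a data frame of class `error_map` with one scanned point per
#'   row: the torsion columns, `e_lam`, `e_oracle` (both as
#'   `deltaE_intra`, kJ/mol), `abs_error` and `nearest_lam_id`.
#'   Scan metadata (increment, fixed slice, oracle id, `u_global`) is
#'   attached as attributes.
#' @export
scan_error_map <- function(ls, spec, increment = 5, fixed = NULL) {
  d <- ls$domain
  scan_dims <- seq_along(d$lower)
  if (!is.null(fixed)) {
    fi <- match(names(fixed), d$names)
    if (anyNA(fi)) stop("fixed names not in the domain: ",
                        paste(names(fixed)[is.na(fi)], collapse = ", "))
    scan_dims <- setdiff(scan_dims, fi)
  }
  axes <- lapply(scan_dims, function(i) {
    span <- d$upper[i] - d$lower[i]
    if (abs(span / increment - round(span / increment)) > 1e-9)
      stop("increment does not divide the span of dimension ", d$names[i])
    if (d$periodic[i]) seq(d$lower[i], d$upper[i] - increment, by = increment)
    else seq(d$lower[i], d$upper[i], by = increment)
  })
  g <- as.matrix(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
  thetas <- matrix(0, nrow(g), domain_dim(d))
  thetas[, scan_dims] <- g
  if (!is.null(fixed)) thetas[, match(names(fixed), d$names)] <-
    matrix(fixed, nrow(g), length(fixed), byrow = TRUE)
  pred <- lamset_predict(ls, thetas)
  e_oracle <- relaxed_energy(spec, thetas) - ls$provenance$u_global
  out <- as.data.frame(thetas)
  names(out) <- d$names
  out$e_lam <- pred$energy
  out$e_oracle <- e_oracle
  out$abs_error <- abs(pred$energy - e_oracle)
  out$nearest_lam_id <- pred$nearest
  structure(out, class = c("error_map", "data.frame"),
            increment = increment, fixed = fixed,
            oracle_id = spec$id, u_global = ls$provenance$u_global)
}

#' Summary statistics of an error map
#'
#' @param map an [scan_error_map()] data frame (or any data frame with
#'   an `abs_error` column and torsion columns first).
#' @param error_threshold level (kJ/mol) for the reported
#'   large-error fraction (default 5).
#' @param relevant_cutoff optional energy level (kJ/mol); when given,
#'   the mean absolute deviation is also reported over the
#'   energetically relevant rows (`e_oracle <= relevant_cutoff`), the
#'   region the adaptive placement criteria are designed to cover.
#' @return list with `n`, `mean_abs_dev`, `max_abs_error`,
#'   `argmax_theta`, `frac_above`, and -- when `relevant_cutoff` is
#'   given -- `n_relevant` and `mean_abs_dev_relevant`.
#' @export
summarize_error_map <- function(map, error_threshold = 5,
                                relevant_cutoff = NULL) {
  if (!nrow(map)) stop("the error map is empty")
  i_max <- which.max(map$abs_error)
  n_theta <- which(names(map) == "e_lam") - 1L
  out <- list(n = nrow(map),
              mean_abs_dev = mean(map$abs_error),
              max_abs_error = map$abs_error[i_max],
              argmax_theta = as.numeric(map[i_max, seq_len(n_theta)]),
              frac_above = mean(map$abs_error > error_threshold))
  if (!is.null(relevant_cutoff)) {
    rel <- map$e_oracle <= relevant_cutoff
    out$n_relevant <- sum(rel)
    out$mean_abs_dev_relevant <-
      if (any(rel)) mean(map$abs_error[rel]) else NA_real_
  }
  out
}

#' Minimum spacing of a LAM set
#'
#' Smallest pairwise [torsion_distance()] between reference
#' conformations -- the resolution a regular grid would need to match.
#'
#' @param ls a [lam_set()] with at least two models.
#' @return distance in degrees.
#' @export
min_spacing <- function(ls) {
  refs <- lamset_refs(ls)
  n <- nrow(refs)
  if (n < 2) stop("min_spacing needs at least two LAMs")
  best <- Inf
  for (i in seq_len(n - 1)) {
    dd <- dist_to_rows(refs[(i + 1):n, , drop = FALSE], refs[i, ],
                       ls$domain)
    best <- min(best, dd)
  }
  best
}

#' Write an error map and its metadata
#'
#' The table goes to CSV; the scan metadata (increment, fixed slice,
#' oracle id, reference energy) goes to a JSON sidecar named
#' `<path>.meta.json`, so downstream plots are reproducible.
#'
#' @param map an [scan_error_map()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_error_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  meta <- list(increment = attr(map, "increment"),
               fixed = as.list(attr(map, "fixed")),
               oracle_id = attr(map, "oracle_id"),
               u_global = attr(map, "u_global"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
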