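LAMSET_FORMAT_VERSION <- 1L

domain_to_list <- function(d) {
  list(names = d$names, lower = d$lower, upper = d$upper,
       periodic = d$periodic, half_spacing = d$half_spacing)
}

domain_from_list <- function(x) {
  torsion_domain(x$lower, x$upper, x$periodic, x$half_spacing,
                 names = x$names)
}

#' Serialize a LAM set to JSON
#'
#' Numbers are written with 17 significant digits, so a write/read
#' round trip reproduces every numeric field bit-identically.
#'
#' @param ls a [lam_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_lamset()]; the schema ships in
#'   `system.file("schemas", "lamset.schema.json", package = "lamadapt")`.
#' @export
write_lamset <- function(ls, path) {
  obj <- list(
    format_version = LAMSET_FORMAT_VERSION,
    domain = domain_to_list(ls$domain),
    u_global = ls$provenance$u_global,
    oracle_id = ls$provenance$oracle_id,
    build_params = ls$provenance$build_params,
    log = as.list(ls$provenance$log),
    lams = lapply(ls$lams, function(l) list(
      theta_ref = l$theta_ref, e_ref = l$e_ref, b = l$b,
      a = as.numeric(t(l$A)),            # row-major
      beta_ref = l$beta_ref,
      c = as.numeric(t(l$C)),            # row-major, rows = dependent DOFs
      n_dep = nrow(l$C),
      payload = l$payload)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

schema_stop <- function(fmt, ...) {
  stop(structure(class = c("lamadapt_schema_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    schema_stop("missing required field '%s' in %s", field, where)
  x[[field]]
}

#' Read a LAM set from JSON
#'
#' Validates the file structurally (required fields, consistent
#' dimensions, symmetric curvature matrices within 1e-9); violations
#' raise an error naming the offending field. Unknown extra fields on a
#' model are folded into its payload, with a message, so files written
#' by newer tools still load.
#'
#' @param path path to a file written by [write_lamset()].
#' @return a [lam_set()].
#' @export
read_lamset <- function(path) {
  if (!file.exists(path)) stop("LAM-set file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  for (f in c("format_version", "domain", "u_global", "oracle_id", "lams"))
    need_field(obj, f, "lamset")
  dom <- obj$domain
  for (f in c("lower", "upper", "periodic", "half_spacing"))
    need_field(dom, f, "lamset$domain")
  d <- domain_from_list(lapply(dom, unlist))
  n <- domain_dim(d)
  known <- c("theta_ref", "e_ref", "b", "a", "beta_ref", "c", "n_dep",
             "payload")
  lams <- lapply(seq_along(obj$lams), function(k) {
    l <- obj$lams[[k]]
    where <- sprintf("lams[[%d]]", k)
    theta_ref <- as.numeric(unlist(need_field(l, "theta_ref", where)))
    if (length(theta_ref) != n)
      schema_stop("%s$theta_ref has length %d, domain has %d dimension(s)",
                  where, length(theta_ref), n)
    a <- as.numeric(unlist(need_field(l, "a", where)))
    if (length(a) != n * n)
      schema_stop("%s$a has %d entries, expected %d", where, length(a), n * n)
    A <- matrix(a, n, n, byrow = TRUE)
    if (max(abs(A - t(A))) > 1e-9)
      schema_stop("%s$a is not symmetric within 1e-9", where)
    A <- (A + t(A)) / 2
    beta_ref <- as.numeric(unlist(l$beta_ref))
    n_dep <- if (!is.null(l$n_dep)) as.integer(l$n_dep) else length(beta_ref)
    cm <- as.numeric(unlist(l$c))
    if (length(cm) != n_dep * n)
      schema_stop("%s$c has %d entries, expected %d", where, length(cm),
                  n_dep * n)
    payload <- if (is.null(l$payload)) list() else l$payload
    extra <- setdiff(names(l), known)
    if (length(extra)) {
      message(sprintf("%s: folding unknown field(s) %s into payload",
                      where, paste(extra, collapse = ", ")))
      payload <- c(payload, l[extra])
    }
    e_ref <- as.numeric(need_field(l, "e_ref", where))
    if (e_ref < -1e-6)
      schema_stop("%s$e_ref = %g is negative beyond tolerance", where, e_ref)
    structure(list(theta_ref = theta_ref, e_ref = e_ref,
                   b = as.numeric(unlist(need_field(l, "b", where))),
                   A = A, beta_ref = beta_ref,
                   C = matrix(cm, n_dep, n, byrow = TRUE),
                   payload = payload),
              class = "lam")
  })
  ls <- lam_set(d, lams, oracle_id = obj$oracle_id,
                u_global = as.numeric(obj$u_global),
                build_params = obj$build_params %||% list())
  ls$provenance$log <- as.character(unlist(obj$log))
  ls
}

#' Serialize a potential specification to JSON
#'
#' @param spec a [potential_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_potential()]; schema in
#'   `system.file("schemas", "potential.schema.json", package = "lamadapt")`.
#' @export
write_potential <- function(spec, path) {
  obj <- list(format_version = 1L, id = spec$id, n_indep = spec$n_indep,
              n_dep = spec$n_dep, const = spec$const,
              fourier = spec$fourier, coupling = spec$coupling,
              dep = lapply(spec$dep, function(m)
                list(beta0 = m$beta0, terms = m$terms)),
              kappa = spec$kappa, quadratic = spec$quadratic)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a potential specification from JSON
#' @param path path to a file written by [write_potential()].
#' @return a [potential_spec()].
#' @export
read_potential <- function(path) {
  if (!file.exists(path)) stop("potential file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  for (f in c("n_indep", "n_dep", "id")) need_field(obj, f, "potential")
  quad <- obj$quadratic
  if (!is.null(quad)) quad <- list(theta0 = unlist(quad$theta0),
                                   curvature = unlist(quad$curvature))
  dep <- lapply(obj$dep, function(m)
    list(beta0 = as.numeric(m$beta0), terms = as.data.frame(m$terms)))
  cols <- function(x) if (length(x) && length(x[[1]])) as.data.frame(x)
                      else NULL
  fourier <- cols(obj$fourier)
  coupling <- cols(obj$coupling)
  potential_spec(obj$n_indep, obj$n_dep, fourier = fourier,
                 coupling = coupling, dep = dep,
                 kappa = as.numeric(unlist(obj$kappa)),
                 quadratic = quad, const = obj$const %||% 0, id = obj$id)
}
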