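#' Natural cubic spline basis with analytic derivatives
#'
#' The longitudinal trajectories of milk yield (MY), body weight (BW) and
#' rumination time (RUM) are modelled on a natural cubic spline of days in
#' milk (DIM). The hazard of culling depends on the analytic first derivative
#' of the fitted trajectories, so the basis is built once as a `spline_spec`
#' object carrying the knots and the natural-constraint projection, and both
#' the basis and its exact derivative are evaluated from it. Beyond the
#' boundary knots the basis continues linearly (the natural condition), so the
#' derivative is constant there — survival times extend well past the 305-DIM
#' observation window and rely on this extrapolation.
#'
#' @name spline_basis
NULL

#' Construct a spline specification from knots
#'
#' @param interior_knots numeric vector of interior knot locations (DIM)
#' @param boundary_knots length-2 numeric, min and max DIM
#' @return object of class `spline_spec` with elements `interior_knots`,
#'   `boundary_knots`, `dim` (number of basis columns, excluding intercept)
#' @export
spline_spec <- function(interior_knots, boundary_knots) {
  interior_knots <- sort(as.numeric(interior_knots))
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2 || boundary_knots[1] >= boundary_knots[2])
    stop("boundary_knots must be (min, max) with min < max")
  if (length(interior_knots) > 0) {
    if (any(interior_knots <= boundary_knots[1]) ||
        any(interior_knots >= boundary_knots[2]))
      stop("interior knots must lie strictly inside the boundary knots")
    if (anyDuplicated(interior_knots))
      stop("duplicate interior knots (degenerate DIM distribution)")
  }
  a <- boundary_knots[1]; b <- boundary_knots[2]
  Aknots <- sort(c(rep(a, 4), interior_knots, rep(b, 4)))
  # natural constraints: zero second derivative at both boundary knots;
  # drop the B-spline intercept column, then project out the constraints
  const <- splines::splineDesign(Aknots, boundary_knots, ord = 4,
                                 derivs = c(2L, 2L))[, -1, drop = FALSE]
  qr_const <- qr(t(const))
  proj <- qr.Q(qr_const, complete = TRUE)[, -(1:2), drop = FALSE]
  spec <- list(
    interior_knots = interior_knots,
    boundary_knots = boundary_knots,
    dim = length(interior_knots) + 1L,
    Aknots = Aknots,
    proj = proj
  )
  class(spec) <- "spline_spec"
  spec
}

#' Knot placement by outcome kind
#'
#' RUM trajectories get a single interior knot at the median observed DIM;
#' MY and BW get three interior knots at the DIM quartiles, to follow the
#' well-defined lactation and body-weight shapes. Boundary knots sit at the
#' observed DIM range. Knots are computed on the pooled cow-day DIM values of
#' the data the model is trained on.
#'
#' @param dim_values pooled observed DIM values (integer days)
#' @param outcome_kind one of "MY", "BW", "RUM"
#' @return a [spline_spec()]
#' @export
make_knots <- function(dim_values, outcome_kind = c("MY", "BW", "RUM")) {
  outcome_kind <- match.arg(outcome_kind)
  dim_values <- as.numeric(dim_values[is.finite(dim_values)])
  if (length(unique(dim_values)) < 10)
    stop("need at least 10 distinct DIM values to place knots")
  interior <- if (outcome_kind == "RUM") {
    unname(quantile(dim_values, 0.5, type = 7))
  } else {
    unname(quantile(dim_values, c(0.25, 0.5, 0.75), type = 7))
  }
  if (anyDuplicated(interior))
    stop("duplicate knots: DIM distribution too degenerate for ",
         outcome_kind)
  spline_spec(interior, range(dim_values))
}

#' Evaluate the natural cubic basis
#'
#' @param t evaluation points (any real; linear extrapolation beyond the
#'   boundary knots)
#' @param spec a [spline_spec()]
#' @param deriv 0 for the basis, 1 for its first derivative
#' @return matrix `length(t)` x `spec$dim`
#' @export
ns_basis <- function(t, spec, deriv = 0L) {
  stopifnot(inherits(spec, "spline_spec"), deriv %in% c(0L, 1L))
  t <- as.numeric(t)
  a <- spec$boundary_knots[1]; b <- spec$boundary_knots[2]
  out <- matrix(0, length(t), spec$dim)
  inside <- t >= a & t <= b
  eval_in <- function(x, d) {
    splines::splineDesign(spec$Aknots, x, ord = 4,
                          derivs = rep(d, length(x)))[, -1, drop = FALSE] %*%
      spec$proj
  }
  if (any(inside)) out[inside, ] <- eval_in(t[inside], deriv)
  # linear continuation: f(t) = f(k) + (t - k) f'(k) outside [a, b]
  for (side in c("lo", "hi")) {
    k <- if (side == "lo") a else b
    idx <- if (side == "lo") t < a else t > b
    if (!any(idx)) next
    f0 <- eval_in(k, 0L)
    f1 <- eval_in(k, 1L)
    out[idx, ] <- if (deriv == 0L) {
      rep(1, sum(idx)) %*% f0 + (t[idx] - k) %*% f1
    } else {
      rep(1, sum(idx)) %*% f1
    }
  }
  out
}

#' @rdname ns_basis
#' @export
ns_basis_deriv <- function(t, spec) ns_basis(t, spec, deriv = 1L)

#' @export
print.spline_spec <- function(x, ...) {
  cat("Natural cubic spline basis\n")
  cat("  interior knots:", paste(signif(x$interior_knots, 4), collapse = ", "),
      "\n")
  cat("  boundary knots:", paste(signif(x$boundary_knots, 4), collapse = ", "),
      "\n")
  cat("  basis dimension:", x$dim, "\n")
  invisible(x)
}

# serialization helpers (fit files store the knots, not the projection)
spec_to_list <- function(spec) {
  list(interior_knots = spec$interior_knots,
       boundary_knots = spec$boundary_knots)
}
spec_from_list <- function(l) {
  spline_spec(unlist(l$interior_knots), unlist(l$boundary_knots))
}
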