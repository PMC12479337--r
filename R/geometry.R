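# Sphere, cluster, shell and gradient-weighted volume computations.
# All lengths are in micrometres (um), all volumes in cubic micrometres (um^3).

#' Unit conversion: cubic micrometres per millilitre
#'
#' One millilitre equals 1e12 um^3. Kept in a single exported constant so the
#' micron-scale geometry and the organ-scale (ml) calibration share one
#' conversion factor.
#'
#' @format A length-one numeric.
#' @export
UM3_PER_ML <- 1e12

#' Volume of a single beta cell
#'
#' A beta cell is modelled as a perfect sphere; the default radius of 5 um
#' (10 um diameter) matches histological measurements and gives a cell volume
#' of about 524 um^3.
#'
#' @param radius Cell radius in um; must be positive. Default 5.
#' @return Volume in um^3: \eqn{(4/3)\pi r^3}.
#' @examples
#' cell_volume()      # ~523.6
#' cell_volume(10)    # ~4188.8
#' @export
cell_volume <- function(radius = 5) {
  stopifnot(is.numeric(radius))
  if (any(radius <= 0)) stop("`radius` must be positive", call. = FALSE)
  (4 / 3) * pi * radius^3
}

#' Equivalent-sphere geometry of a beta-cell cluster
#'
#' An islet (cluster of `n_cells` beta cells) is modelled as a single sphere
#' whose volume equals the summed volume of its cells, assuming no
#' extracellular space or packing voids. The equivalent radius is therefore
#' `cell_radius * n_cells^(1/3)`.
#'
#' @param n_cells Number of beta cells in the cluster; integer >= 1.
#' @param cell_radius Single-cell radius in um. Default 5.
#' @return An object of class `cluster_geometry`: a list with `n_cells`,
#'   `radius` (um) and `volume` (um^3).
#' @examples
#' cluster_geometry(1000)   # radius exactly 50 um
#' @export
cluster_geometry <- function(n_cells, cell_radius = 5) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L)
  if (n_cells < 1 || n_cells != round(n_cells)) {
    stop("`n_cells` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      n_cells = as.integer(n_cells),
      radius  = cell_radius * n_cells^(1 / 3),
      volume  = n_cells * cell_volume(cell_radius)
    ),
    class = "cluster_geometry"
  )
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat(sprintf(
    "<cluster_geometry> %d cells, radius %.4g um, volume %.6g um^3\n",
    x$n_cells, x$radius, x$volume
  ))
  invisible(x)
}

#' Volume of a concentric spherical shell
#'
#' The constant-shell model of insulin action: insulin acts homogeneously
#' within a shell of the given thickness beyond the outer edge of the cluster,
#' so the affected volume is the difference between the outer sphere (radius
#' `inner_radius + thickness`) and the cluster sphere.
#'
#' @param inner_radius Cluster radius in um; positive.
#' @param thickness Shell thickness in um; non-negative.
#' @return Shell volume in um^3.
#' @examples
#' shell_volume(5, 20)   # ~64927 um^3 around a single beta cell
#' @export
shell_volume <- function(inner_radius, thickness) {
  stopifnot(is.numeric(inner_radius), is.numeric(thickness))
  if (any(inner_radius <= 0)) stop("`inner_radius` must be positive", call. = FALSE)
  if (any(thickness < 0)) stop("`thickness` must be non-negative", call. = FALSE)
  (4 / 3) * pi * ((inner_radius + thickness)^3 - inner_radius^3)
}

#' Effective volume under an exponential insulin gradient
#'
#' The insulin-gradient model: insulin action is strongest at the cluster
#' edge and decays exponentially with distance, with decay length `lambda`.
#' The effective (distance-weighted) affected volume is
#' \deqn{\int_{r_0}^{r_0 + T\lambda} 4\pi r^2 e^{-(r - r_0)/\lambda}\,dr}
#' with the integral truncated at `T = truncation_multiple` decay lengths
#' (default 5, where the weight has fallen below 1%). The closed form is
#' \deqn{4\pi\left[\lambda^3(2 - e^{-T}(T^2+2T+2)) +
#'   2 r_0 \lambda^2 (1 - e^{-T}(T+1)) + r_0^2 \lambda (1 - e^{-T})\right].}
#'
#' @param inner_radius Cluster radius \eqn{r_0} in um; positive.
#' @param decay_length Decay length \eqn{\lambda} in um; positive.
#' @param truncation_multiple Upper integration limit in units of
#'   `decay_length`; default 5.
#' @return Effective affected volume in um^3.
#' @seealso [gradient_effective_volume_quadrature()] for the numerical oracle.
#' @examples
#' gradient_effective_volume(5, 10)   # ~37175 um^3
#' @export
gradient_effective_volume <- function(inner_radius, decay_length,
                                      truncation_multiple = 5) {
  stopifnot(is.numeric(inner_radius), is.numeric(decay_length))
  if (any(inner_radius <= 0)) stop("`inner_radius` must be positive", call. = FALSE)
  if (any(decay_length <= 0)) stop("`decay_length` must be positive", call. = FALSE)
  if (truncation_multiple <= 0) {
    stop("`truncation_multiple` must be positive", call. = FALSE)
  }
  r0 <- inner_radius
  lam <- decay_length
  Tm <- truncation_multiple
  eT <- exp(-Tm)
  4 * pi * (
    lam^3 * (2 - eT * (Tm^2 + 2 * Tm + 2)) +
    2 * r0 * lam^2 * (1 - eT * (Tm + 1)) +
    r0^2 * lam * (1 - eT)
  )
}

#' Gradient effective volume by adaptive quadrature
#'
#' Numerically integrates the gradient-model integrand
#' \eqn{4\pi r^2 e^{-(r-r_0)/\lambda}} from \eqn{r_0} to
#' \eqn{r_0 + T\lambda} with [stats::integrate()]. Serves as an independent
#' oracle for [gradient_effective_volume()]; intended for testing, not
#' production sweeps.
#'
#' @inheritParams gradient_effective_volume
#' @param rel_tol Requested relative accuracy of the quadrature.
#' @return Effective affected volume in um^3.
#' @export
gradient_effective_volume_quadrature <- function(inner_radius, decay_length,
                                                 truncation_multiple = 5,
                                                 rel_tol = 1e-12) {
  if (inner_radius <= 0) stop("`inner_radius` must be positive", call. = FALSE)
  if (decay_length <= 0) stop("`decay_length` must be positive", call. = FALSE)
  integrand <- function(r) {
    4 * pi * r^2 * exp(-(r - inner_radius) / decay_length)
  }
  res <- stats::integrate(
    integrand,
    lower = inner_radius,
    upper = inner_radius + truncation_multiple * decay_length,
    rel.tol = rel_tol, abs.tol = 0
  )
  if (res$message != "OK") {
    stop("quadrature did not converge: ", res$message, call. = FALSE)
  }
  res$value
}

#' Monte-Carlo estimate of a spherical-shell volume
#'
#' Stochastic oracle for [shell_volume()]: samples points uniformly in the
#' bounding cube of the outer sphere, counts the fraction landing inside the
#' shell, and scales by the cube volume. The binomial standard error of the
#' estimate is returned alongside it.
#'
#' @inheritParams shell_volume
#' @param n_samples Number of uniform samples; >= 1.
#' @param seed Integer seed for the local random stream. The global RNG state
#'   is left untouched.
#' @return A list of class `mc_volume` with `estimate` (um^3), `std_error`
#'   (um^3), `n_samples` and `seed`.
#' @export
monte_carlo_shell_volume <- function(inner_radius, thickness,
                                     n_samples = 1e6, seed = 1L) {
  if (inner_radius <= 0) stop("`inner_radius` must be positive", call. = FALSE)
  if (thickness < 0) stop("`thickness` must be non-negative", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  outer <- inner_radius + thickness
  cube_volume <- (2 * outer)^3
  # local RNG stream; do not disturb the caller's .Random.seed
  hits <- local({
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    n <- as.integer(n_samples)
    x <- stats::runif(n, -outer, outer)
    y <- stats::runif(n, -outer, outer)
    z <- stats::runif(n, -outer, outer)
    d2 <- x^2 + y^2 + z^2
    sum(d2 <= outer^2 & d2 >= inner_radius^2)
  })
  p <- hits / n_samples
  structure(
    list(
      estimate   = cube_volume * p,
      std_error  = cube_volume * sqrt(p * (1 - p) / n_samples),
      n_samples  = as.integer(n_samples),
      seed       = as.integer(seed)
    ),
    class = "mc_volume"
  )
}

#' @export
print.mc_volume <- function(x, ...) {
  cat(sprintf(
    "<mc_volume> %.6g +/- %.3g um^3 (n = %d, seed = %d)\n",
    x$estimate, x$std_error, x$n_samples, x$seed
  ))
  invisible(x)
}
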