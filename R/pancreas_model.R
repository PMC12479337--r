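# Whole-pancreas model: beta-cell density -> pancreas volume, mixtures of
# cluster sizes, reference-volume threshold scans, and inversion from an
# observed volume back to density.

#' Organ-scale calibration
#'
#' Anchors the micron-scale geometry to organ volumes: `baseline_volume` is
#' the pancreas volume with no beta cells (60 ml, the longstanding-T1D
#' average from meta-analysis), `reference_volume` the non-diabetic volume
#' (90 ml), and `density_max` the maximum beta-cell volume fraction (3%).
#'
#' `density_basis` selects what the density is a fraction *of*. The default
#' `"reference"` takes total beta-cell volume as `density * reference_volume`,
#' so the predicted volume is affine in density. The self-consistent
#' alternative `"modeled"` defines density relative to the predicted volume
#' itself, giving `V = V0 / (1 - d (1 + k))`; it is provided for sensitivity
#' analysis and is not the default.
#'
#' @param baseline_volume Pancreas volume in ml when beta-cell density is
#'   zero. Default 60.
#' @param reference_volume Non-diabetic reference pancreas volume in ml.
#'   Default 90. Must exceed `baseline_volume`.
#' @param density_max Upper end of the modelled beta-cell density range
#'   (volume fraction). Default 0.03.
#' @param density_basis `"reference"` (default) or `"modeled"`; see Details.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(baseline_volume = 60, reference_volume = 90,
                               density_max = 0.03,
                               density_basis = c("reference", "modeled")) {
  density_basis <- match.arg(density_basis)
  stopifnot(is.numeric(baseline_volume), is.numeric(reference_volume),
            is.numeric(density_max))
  if (baseline_volume <= 0 || reference_volume <= baseline_volume) {
    stop("need 0 < baseline_volume < reference_volume", call. = FALSE)
  }
  if (density_max <= 0 || density_max >= 1) {
    stop("`density_max` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      baseline_volume  = baseline_volume,
      reference_volume = reference_volume,
      density_max      = density_max,
      density_basis    = density_basis
    ),
    class = "calibration_config"
  )
}

#' @export
print.calibration_config <- function(x, ...) {
  cat(sprintf(
    "<calibration_config> V0 = %g ml, V_ref = %g ml, density <= %g (%s basis)\n",
    x$baseline_volume, x$reference_volume, x$density_max, x$density_basis
  ))
  invisible(x)
}

#' Weighted mixture of beta-cell cluster sizes
#'
#' Describes the islet-size heterogeneity of a pancreas as a set of cluster
#' sizes with weights. Weights are fractions of TOTAL BETA-CELL VOLUME held
#' in clusters of each size (not counts of clusters). Weights within 1e-6 of
#' summing to one are renormalised with a warning; larger deviations are an
#' error.
#'
#' @param n_cells Integer vector of distinct cluster sizes (cells), each >= 1.
#' @param weights Numeric vector of non-negative volume fractions, same
#'   length, summing to 1.
#' @param id Optional label used in sweep output. Default `"custom"`.
#' @return An object of class `size_distribution`.
#' @examples
#' single_cells <- size_distribution(1, 1)
#' autopsy_mix  <- mixed_distribution()
#' @export
size_distribution <- function(n_cells, weights, id = "custom") {
  stopifnot(is.numeric(n_cells), is.numeric(weights),
            length(n_cells) == length(weights), length(n_cells) >= 1L)
  if (any(n_cells < 1) || any(n_cells != round(n_cells))) {
    stop("cluster sizes must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(n_cells)) {
    stop("cluster sizes must be distinct", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (abs(s - 1) > 1e-6) {
    stop("weights sum to ", format(s), ", not 1", call. = FALSE)
  }
  if (s != 1) {
    warning("weights sum to ", format(s, digits = 12),
            "; renormalising", call. = FALSE)
    weights <- weights / s
  }
  structure(
    list(n_cells = as.integer(n_cells), weights = weights, id = id),
    class = "size_distribution"
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> '%s'\n", x$id))
  for (i in seq_along(x$n_cells)) {
    cat(sprintf("  %5d cells : %5.1f%% of beta-cell volume\n",
                x$n_cells[i], 100 * x$weights[i]))
  }
  invisible(x)
}

#' Autopsy-style mixed islet-size distribution
#'
#' The heterogeneous cluster-size mixture used for the expansion-magnitude
#' analyses: 5% of beta-cell volume in single cells, 10% in 10-cell
#' clusters, 20% in 25-cell, 40% in 100-cell, 20% in 250-cell and 5% in
#' 1000-cell clusters.
#'
#' @return A [size_distribution()] with id `"autopsy_mixed"`.
#' @export
mixed_distribution <- function() {
  size_distribution(
    n_cells = c(1, 10, 25, 100, 250, 1000),
    weights = c(0.05, 0.10, 0.20, 0.40, 0.20, 0.05),
    id = "autopsy_mixed"
  )
}

#' Mixture-averaged expansion ratio
#'
#' The effective added-acinar-volume per unit beta-cell volume for a mixture
#' of cluster sizes: the weighted mean of the per-size [expansion_ratio()],
#' with weights the beta-cell-volume fractions of the distribution.
#'
#' @param dist A [size_distribution()].
#' @param action A [shell_action()] or [gradient_action()].
#' @param expansion An [expansion_spec()] or bare fraction. Default 1.
#' @param cell_radius Single-cell radius in um. Default 5.
#' @return Dimensionless effective ratio `k_eff`.
#' @export
mixture_expansion_ratio <- function(dist, action, expansion = 1,
                                    cell_radius = 5) {
  stopifnot(inherits(dist, "size_distribution"))
  ratios <- vapply(
    dist$n_cells,
    function(n) expansion_ratio(n, action, expansion, cell_radius),
    numeric(1)
  )
  sum(dist$weights * ratios)
}

#' Predicted pancreas volume at a given beta-cell density
#'
#' Composes the calibration with the mixture expansion ratio. Under the
#' default `"reference"` density basis the total beta-cell volume is
#' `d * V_ref` and
#' \deqn{V(d) = V_0 + d\,V_{ref}\,(1 + k_{eff}),}
#' i.e. baseline exocrine tissue, plus the beta-cell volume itself, plus the
#' insulin-driven acinar increment `d * V_ref * k_eff`; affine in density.
#' Under the `"modeled"` basis density is relative to the predicted volume,
#' giving `V = V0 / (1 - d (1 + k_eff))` (valid while `d (1 + k_eff) < 1`).
#'
#' @param density Beta-cell density (volume fraction); within
#'   `[0, calib$density_max]`. Vectorised.
#' @param calib A [calibration_config()].
#' @inheritParams mixture_expansion_ratio
#' @return Pancreas volume in ml.
#' @examples
#' calib <- calibration_config()
#' pancreas_volume(0.03, calib, size_distribution(1, 1), shell_action(10))
#' # 132.9 ml: 60 + 0.03*90*(1 + 26)
#' @export
pancreas_volume <- function(density, calib, dist, action, expansion = 1) {
  stopifnot(inherits(calib, "calibration_config"))
  if (any(density < 0 | density > calib$density_max)) {
    stop("`density` must lie in [0, ", calib$density_max, "]", call. = FALSE)
  }
  k_eff <- mixture_expansion_ratio(dist, action, expansion)
  if (calib$density_basis == "reference") {
    calib$baseline_volume + density * calib$reference_volume * (1 + k_eff)
  } else {
    load <- density * (1 + k_eff)
    if (any(load >= 1)) {
      stop("modeled-basis volume diverges: density * (1 + k_eff) >= 1",
           call. = FALSE)
    }
    calib$baseline_volume / (1 - load)
  }
}

#' Pancreas-volume curve over a density grid
#'
#' Element-wise [pancreas_volume()] over a density grid, returned as a tidy
#' data frame with the configuration recorded in each row. Under the default
#' basis the curve is a straight line with intercept `baseline_volume` and
#' slope `reference_volume * (1 + k_eff)` ml per unit density.
#'
#' @param density_grid Numeric vector of densities in
#'   `[0, calib$density_max]`. Default `seq(0, calib$density_max, by = 0.001)`.
#' @inheritParams pancreas_volume
#' @return A data frame of class `volume_curve` with columns `density`,
#'   `volume_ml`, `model`, `extent_um`, `expansion_fraction`,
#'   `distribution_id`, plus attributes `k_eff` and `calibration`.
#' @export
volume_curve <- function(calib, dist, action, expansion = 1,
                         density_grid = NULL) {
  if (is.null(density_grid)) {
    density_grid <- seq(0, calib$density_max, by = 0.001)
  }
  vols <- pancreas_volume(density_grid, calib, dist, action, expansion)
  out <- data.frame(
    density            = density_grid,
    volume_ml          = vols,
    model              = if (inherits(action, "shell_action")) "shell" else "gradient",
    extent_um          = action_extent(action),
    expansion_fraction = as_expansion(expansion)$fraction,
    distribution_id    = dist$id,
    stringsAsFactors   = FALSE
  )
  attr(out, "k_eff") <- mixture_expansion_ratio(dist, action, expansion)
  attr(out, "calibration") <- calib
  class(out) <- c("volume_curve", class(out))
  out
}

#' Does the modelled pancreas reach the non-diabetic reference volume?
#'
#' Evaluates the predicted volume at the maximum modelled density and
#' compares it to the reference volume (the dashed 90-ml line of the
#' figures).
#'
#' @inheritParams pancreas_volume
#' @return A list with `reaches` (logical: predicted volume at
#'   `density_max` >= reference) and `margin_ml` (predicted minus reference,
#'   ml).
#' @export
reaches_reference <- function(calib, dist, action, expansion = 1) {
  v <- pancreas_volume(calib$density_max, calib, dist, action, expansion)
  list(reaches = v >= calib$reference_volume,
       margin_ml = v - calib$reference_volume)
}

#' Estimate beta-cell density from an observed pancreas volume
#'
#' Inverts the volume model: under the default basis
#' `d = (V_obs - V0) / (V_ref (1 + k_eff))`; under the modeled basis
#' `d = (V_obs - V0) / (V_obs (1 + k_eff))`. The round trip
#' `estimate_density(pancreas_volume(d, ...), ...) == d` holds to floating
#' precision. This is the imaging use case: translate a radiologically
#' measured pancreas volume into a relative beta-cell-mass estimate.
#'
#' @param observed_volume Measured pancreas volume in ml; must be >=
#'   `calib$baseline_volume`.
#' @inheritParams pancreas_volume
#' @return Estimated density (volume fraction).
#' @export
estimate_density <- function(observed_volume, calib, dist, action,
                             expansion = 1) {
  stopifnot(inherits(calib, "calibration_config"))
  if (any(observed_volume < calib$baseline_volume)) {
    stop("`observed_volume` is below the beta-cell-free baseline of ",
         calib$baseline_volume, " ml", call. = FALSE)
  }
  k_eff <- mixture_expansion_ratio(dist, action, expansion)
  if (calib$density_basis == "reference") {
    (observed_volume - calib$baseline_volume) /
      (calib$reference_volume * (1 + k_eff))
  } else {
    (observed_volume - calib$baseline_volume) /
      (observed_volume * (1 + k_eff))
  }
}

#' Number of clusters of each size at a given density
#'
#' Diagnostic linking the continuous density axis to discrete cluster
#' counts: the beta-cell volume assigned to each mixture component divided
#' by the volume of one cluster of that size. Counts are real numbers, not
#' rounded. Total beta-cell volume is conserved:
#' `sum(count * cluster volume) = d * V_ref`.
#'
#' @inheritParams pancreas_volume
#' @param cell_radius Single-cell radius in um.
#' @return A data frame with columns `n_cells` and `count`.
#' @export
cluster_counts <- function(density, calib, dist, cell_radius = 5) {
  stopifnot(inherits(calib, "calibration_config"),
            inherits(dist, "size_distribution"),
            length(density) == 1L)
  if (density < 0 || density > calib$density_max) {
    stop("`density` must lie in [0, ", calib$density_max, "]", call. = FALSE)
  }
  total_beta_um3 <- density * calib$reference_volume * UM3_PER_ML
  cluster_vols <- vapply(
    dist$n_cells,
    function(n) cluster_geometry(n, cell_radius)$volume,
    numeric(1)
  )
  data.frame(
    n_cells = dist$n_cells,
    count   = dist$weights * total_beta_um3 / cluster_vols
  )
}
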