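#' Microstructure turbulence profile
#'
#' Dissipation rate epsilon (W kg^-1) and squared buoyancy frequency N^2
#' (s^-2) on a regular 5-m depth grid, as reported by CTD-attached
#' fast-response thermistors. When the instrument file carries no N^2,
#' supply one computed from the cast via [buoyancy_frequency_sq()].
#'
#' @param depth depths, m, regular 5-m spacing, increasing.
#' @param epsilon dissipation rate, W kg^-1, >= 0.
#' @param n_sq squared buoyancy frequency, s^-2 (may be <= 0 where the
#'   water column is unstratified; those bins are masked downstream).
#' @return object of class `"turbulence_profile"`.
#' @export
turbulence_profile <- function(depth, epsilon, n_sq) {
  depth <- as.numeric(depth)
  if (length(depth) >= 2L && any(abs(diff(depth) - 5) > 1e-9))
    stop("turbulence_profile: depth grid must have 5-m spacing")
  stopifnot(length(epsilon) == length(depth), length(n_sq) == length(depth))
  if (any(epsilon < 0, na.rm = TRUE))
    stop("turbulence_profile: epsilon must be >= 0")
  structure(list(depth = depth, epsilon = as.numeric(epsilon),
                 n_sq = as.numeric(n_sq)),
            class = "turbulence_profile")
}

#' Osborn vertical eddy diffusivity
#'
#' Kz = 0.2 * epsilon / N^2, with mixing efficiency 0.2. Bins where
#' N^2 <= 0 (or is missing) are masked invalid rather than allowed to
#' produce infinities; the masked fraction is attached as an attribute.
#'
#' @param turb a [turbulence_profile()].
#' @param mixing_efficiency dimensionless mixing efficiency (default 0.2).
#' @return data.frame: `depth` (m), `kz` (m^2 s^-1, NA where masked),
#'   `valid` (logical); attribute `"masked_fraction"`.
#' @export
osborn_diffusivity <- function(turb, mixing_efficiency = 0.2) {
  valid <- !is.na(turb$n_sq) & turb$n_sq > 0 & !is.na(turb$epsilon)
  kz <- rep(NA_real_, length(turb$depth))
  kz[valid] <- mixing_efficiency * turb$epsilon[valid] / turb$n_sq[valid]
  out <- data.frame(depth = turb$depth, kz = kz, valid = valid)
  attr(out, "masked_fraction") <- 1 - mean(valid)
  out
}

#' Linear interpolation of a sampled concentration onto a 5-m grid
#'
#' Bottle concentrations are sampled at 9 discrete depths; the flux
#' calculation needs them on the same 5-m grid as Kz. Interpolation is
#' linear between the shallowest and deepest samples; no extrapolation
#' (grid points outside the sampled range are NA).
#'
#' @param cast a [cast()].
#' @param constituent name of the concentration to interpolate.
#' @param grid target depths, m (default 0-200 m every 5 m).
#' @return data.frame: `depth`, `value` (mol m^-3, NA outside range).
#' @export
interpolate_concentration_5m <- function(cast, constituent,
                                         grid = seq(0, 200, by = 5)) {
  x <- cast$conc[[constituent]]
  if (is.null(x)) stop("constituent '", constituent, "' not in cast")
  keep <- !is.na(x)
  z <- cast$depth[keep]; x <- x[keep]
  if (length(z) < 2L) stop("interpolate_concentration_5m: need >= 2 samples")
  v <- stats::approx(z, x, xout = grid, rule = 1)$y
  data.frame(depth = grid, value = v)
}

#' Vertical gradient on a regular grid
#'
#' Centered difference `(x[i+1] - x[i-1]) / (2 dz)` at interior points,
#' one-sided at the ends, with z positive downward, so a concentration
#' increasing with depth has a positive gradient. NA-safe: a gradient is
#' NA wherever a stencil value is missing.
#'
#' @param values values on the grid.
#' @param dz grid spacing, m (default 5).
#' @return gradient, per metre (mol m^-4 for mol m^-3 input).
#' @export
vertical_gradient <- function(values, dz = 5) {
  n <- length(values)
  if (n < 2L) stop("vertical_gradient: need >= 2 grid points")
  g <- rep(NA_real_, n)
  g[1] <- (values[2] - values[1]) / dz
  g[n] <- (values[n] - values[n - 1]) / dz
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (values[i + 1] - values[i - 1]) / (2 * dz)
  }
  g
}

#' Turbulent diffusive flux profile
#'
#' F_X = Kz * dX/dz, converted from mol m^-2 s^-1 to mol m^-2 d^-1
#' (x 86 400). With z positive downward and the flux reported as upward
#' supply, a positive gradient (concentration increasing with depth)
#' yields a positive (upward) flux; negative gradients give negative
#' (downward) fluxes, which are retained, not clipped.
#'
#' @param kz data.frame from [osborn_diffusivity()].
#' @param gradient gradient values aligned with `kz$depth`, mol m^-4.
#' @return data.frame: `depth`, `flux` (mol m^-2 d^-1, NA where masked),
#'   `gradient`, `valid`.
#' @export
diffusive_flux_profile <- function(kz, gradient) {
  if (length(gradient) != nrow(kz))
    stop("diffusive_flux_profile: gradient not aligned with Kz grid")
  flux <- kz$kz * gradient * 86400
  data.frame(depth = kz$depth, flux = flux, gradient = gradient,
             valid = kz$valid & !is.na(flux))
}

#' Layer-mean flux with confidence interval
#'
#' Arithmetic (unweighted) mean of the valid 5-m flux values with depth
#' strictly inside `(top, bottom]`; the two budget layers are MLD-100 m
#' (supply into the mixed layer, excluded from budget terms) and
#' 100-200 m (upward supply into the euphotic zone).
#'
#' @param flux data.frame from [diffusive_flux_profile()].
#' @param top,bottom layer bounds, m.
#' @param layer optional label stored in the result.
#' @return list of class `"layer_flux"`: `layer`, `value` ([uncertain()],
#'   mol m^-2 d^-1), `n_points`, `empty` flag.
#' @export
layer_mean_flux <- function(flux, top, bottom, layer = NULL) {
  sel <- flux$depth > top & flux$depth <= bottom & flux$valid &
    !is.na(flux$flux)
  vals <- flux$flux[sel]
  if (length(vals) == 0L) {
    return(structure(list(layer = layer, value = uncertain(NA_real_, NA_real_),
                          n_points = 0L, empty = TRUE),
                     class = "layer_flux"))
  }
  structure(list(layer = layer, value = mean_ci(vals),
                 n_points = length(vals), empty = FALSE),
            class = "layer_flux")
}

#' @export
print.layer_flux <- function(x, ...) {
  if (x$empty) cat("<layer_flux>", x$layer, ": no valid points\n")
  else cat("<layer_flux>", x$layer, ":", format(x$value, 3),
           "mol m-2 d-1 over", x$n_points, "points\n")
  invisible(x)
}

#' Per-cast flux pipeline: cast + turbulence to layer-mean fluxes
#'
#' Convenience wrapper running the full per-cast chain: Osborn
#' diffusivity, 5-m concentration interpolation, centered-difference
#' gradient, flux profile, and layer means for MLD-100 m and 100-200 m.
#'
#' @param cast a [cast()] (after detection-limit substitution).
#' @param turb a [turbulence_profile()] for the same station/date.
#' @param constituents constituent names to process.
#' @param mld mixed layer depth, m (computed from the cast if missing).
#' @return list: `mld`, per-constituent list with `profile` (flux
#'   data.frame) and layer results `mld_100` and `l100_200`.
#' @export
cast_fluxes <- function(cast, turb, constituents = c("dic", "nn", "po4"),
                        mld = NULL) {
  if (is.null(mld)) mld <- compute_mld(cast)$mld
  kz <- osborn_diffusivity(turb)
  out <- list(mld = mld)
  for (cn in constituents) {
    conc <- interpolate_concentration_5m(cast, cn, grid = turb$depth)
    grad <- vertical_gradient(conc$value, dz = 5)
    fx <- diffusive_flux_profile(kz, grad)
    out[[cn]] <- list(
      profile = fx,
      mld_100 = layer_mean_flux(fx, mld, 100, "MLD_to_100"),
      l100_200 = layer_mean_flux(fx, 100, 200, "100_to_200"))
  }
  out
}
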