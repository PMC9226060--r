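#' Normative radial thickness profile for an inner retinal layer
#'
#' The ganglion cell layer (GCL) and inner plexiform layer (IPL) follow a
#' rotationally symmetric "bull's-eye": nearly absent at the foveal pit, they
#' peak where ganglion cell somas are stacked in multiple layers (about
#' 4-5 degrees of eccentricity) and thin rapidly beyond about 8 degrees, where
#' somas form a single layer, down to a peripheral floor.
#'
#' The profile rises from `foveal_thickness` to `peak_thickness` as a
#' gamma-shaped curve `(e/e_p)^shape * exp(shape * (1 - e/e_p))` and decays
#' beyond the peak as a Gaussian with scale `decay_scale` toward
#' `peripheral_floor`; both pieces meet the peak with zero slope, so the
#' profile is continuous and smooth.
#'
#' Default parameters (micrometres, degrees) give a healthy posterior-pole
#' grid mean of roughly 32 um for the GCL and 30 um for the IPL.
#'
#' @param layer `"GCL"` or `"IPL"`.
#' @param peak_thickness,peak_eccentricity,foveal_thickness,peripheral_floor,decay_scale,shape
#'   Profile parameters; defaults depend on `layer`.
#' @return An object of class `normative_profile`.
#' @export
normative_profile <- function(layer = c("GCL", "IPL"),
                              peak_thickness = NULL,
                              peak_eccentricity = NULL,
                              foveal_thickness = NULL,
                              peripheral_floor = NULL,
                              decay_scale = NULL,
                              shape = 2.5) {
  layer <- match.arg(layer)
  def <- if (layer == "GCL") {
    list(peak = 55, ecc = 4.5, fov = 8, floor = 20, decay = 4)
  } else {
    list(peak = 44, ecc = 4.0, fov = 12, floor = 21, decay = 4.5)
  }
  p <- structure(
    list(layer = layer,
         peak_thickness = peak_thickness %||% def$peak,
         peak_eccentricity = peak_eccentricity %||% def$ecc,
         foveal_thickness = foveal_thickness %||% def$fov,
         peripheral_floor = peripheral_floor %||% def$floor,
         decay_scale = decay_scale %||% def$decay,
         shape = shape),
    class = "normative_profile")
  stopifnot(p$peak_thickness >= p$foveal_thickness,
            p$peak_thickness >= p$peripheral_floor,
            p$peak_eccentricity > 0, p$decay_scale > 0)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a normative thickness profile
#'
#' @param profile A `normative_profile`.
#' @param x,y Retinal coordinates in degrees (vectors allowed).
#' @return Thickness in micrometres, always non-negative.
#' @export
normative_thickness <- function(profile, x, y) {
  e <- sqrt(x^2 + y^2)
  ep <- profile$peak_eccentricity
  a <- profile$shape
  rising <- profile$foveal_thickness +
    (profile$peak_thickness - profile$foveal_thickness) *
    (e / ep)^a * exp(a * (1 - e / ep))
  falling <- profile$peripheral_floor +
    (profile$peak_thickness - profile$peripheral_floor) *
    exp(-((e - ep) / profile$decay_scale)^2)
  pmax(ifelse(e <= ep, rising, falling), 0)
}

#' Describe a pattern of localized glaucomatous damage
#'
#' Glaucomatous loss in the macula follows arcuate nerve fibre bundles: it is
#' confined to one hemiretina (never crossing the horizontal raphe) and occupies
#' a sector of polar angle within an eccentricity band. The damage fraction is
#' the product of smooth angular and eccentricity windows times `depth`;
#' windows are cubic smoothsteps with compact support, so damage is exactly
#' `depth` well inside the pattern and exactly zero beyond `edge_softness/2`
#' outside its nominal edges.
#'
#' @param hemiretina `"superior"` or `"inferior"` (retinal orientation).
#' @param angular_extent Width of the sector in polar degrees.
#' @param eccentricity_band Numeric length 2: inner and outer eccentricity of
#'   the band, degrees.
#' @param depth Maximal fraction of thickness lost, in `[0, 1]`.
#' @param edge_softness Width of the smooth edge, degrees (arc length for the
#'   angular edge).
#' @param center_angle Polar angle (degrees, counter-clockwise from the
#'   temporal-field axis) of the sector centre; defaults to the middle of the
#'   hemiretina (90 for superior, 270 for inferior).
#' @return An object of class `damage_pattern`.
#' @export
damage_pattern <- function(hemiretina = c("inferior", "superior"),
                           angular_extent = 100,
                           eccentricity_band = c(2, 9),
                           depth = 0.7,
                           edge_softness = 1.5,
                           center_angle = NULL) {
  hemiretina <- match.arg(hemiretina)
  stopifnot(depth >= 0, depth <= 1, angular_extent > 0,
            length(eccentricity_band) == 2L,
            eccentricity_band[1L] <= eccentricity_band[2L],
            edge_softness >= 0)
  center_angle <- center_angle %||% if (hemiretina == "superior") 90 else 270
  structure(list(hemiretina = hemiretina, angular_extent = angular_extent,
                 eccentricity_band = as.numeric(eccentricity_band),
                 depth = depth, edge_softness = edge_softness,
                 center_angle = center_angle),
            class = "damage_pattern")
}

# cubic smoothstep: 0 for u <= 0, 1 for u >= 1
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# compact-support window over [lo, hi] with edge width s
edge_window <- function(t, lo, hi, s) {
  if (s <= 0) return(as.numeric(t >= lo & t <= hi))
  smoothstep((t - (lo - s / 2)) / s) * smoothstep(((hi + s / 2) - t) / s)
}

#' Damage fraction at retinal coordinates
#'
#' Evaluates the combined damage of a list of [damage_pattern()]s at retinal
#' points. Overlapping patterns combine as complementary products
#' (`1 - prod(1 - d_i)`), so the fraction stays in `[0, 1]`. Damage is clamped
#' to zero in the hemiretina opposite each pattern: bundles do not cross the
#' horizontal raphe.
#'
#' @param damage A `damage_pattern`, a list of them, or `NULL`/empty list for a
#'   healthy eye.
#' @param x,y Retinal coordinates in degrees (vectors allowed).
#' @return Damage fraction in `[0, 1]`, same length as `x`.
#' @export
damage_fraction <- function(damage, x, y) {
  if (inherits(damage, "damage_pattern")) damage <- list(damage)
  if (is.null(damage) || length(damage) == 0L) return(rep(0, length(x)))
  e <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) * 180 / pi
  keep <- rep(1, length(x))
  for (pat in damage) {
    dth <- ((theta - pat$center_angle + 180) %% 360) - 180
    mid_e <- max(mean(pat$eccentricity_band), 1)
    s_ang <- pat$edge_softness / mid_e * 180 / pi
    w <- edge_window(abs(dth), -Inf, pat$angular_extent / 2, s_ang) *
      edge_window(e, pat$eccentricity_band[1L], pat$eccentricity_band[2L],
                  pat$edge_softness)
    w[if (pat$hemiretina == "superior") y <= 0 else y >= 0] <- 0
    keep <- keep * (1 - pat$depth * w)
  }
  1 - keep
}

#' Displace a stimulus location to its ganglion cell position
#'
#' In the central retina, ganglion cells are displaced radially outward from
#' the photoreceptors they serve, by up to about 2 degrees for the innermost
#' 10-2 locations. The displacement applied is
#' `dmax * exp(-eccentricity / tau)` along the radial direction, and zero at or
#' beyond 8 degrees of eccentricity, where photoreceptors and ganglion cells
#' are vertically aligned.
#'
#' @param x,y Retinal coordinates in degrees (vectors allowed).
#' @param dmax Maximal displacement, degrees, in `[0, 3]`.
#' @param tau Decay scale of the displacement with eccentricity, degrees.
#' @return A two-column matrix of displaced coordinates.
#' @export
displace_to_rgc <- function(x, y, dmax = 2, tau = 3) {
  stopifnot(dmax >= 0, dmax <= 3, tau > 0)
  e <- sqrt(x^2 + y^2)
  d <- ifelse(e >= 8 | e == 0, 0, dmax * exp(-e / tau))
  scale <- ifelse(e > 0, (e + d) / e, 1)
  cbind(x = x * scale, y = y * scale)
}

#' Healthy visual field sensitivity profile
#'
#' Normal sensitivity declines mildly with eccentricity; the default is
#' 33 dB at fixation falling by 0.1 dB per degree.
#'
#' @param eccentricity Degrees from fixation.
#' @param base_db Sensitivity at fixation, dB.
#' @param slope_db_per_deg Decline per degree of eccentricity.
#' @return Sensitivity in dB.
#' @export
healthy_sensitivity <- function(eccentricity, base_db = 33,
                                slope_db_per_deg = 0.1) {
  base_db - slope_db_per_deg * eccentricity
}
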