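#' Acquisition protocol
#'
#' Camera geometry and timing of a SPECT acquisition: parallel-beam
#' projections at equally spaced angles over a (default full) circular
#' orbit. The defaults mirror a clinical protocol: 120 angles over 360
#' degrees at 15 s per projection on a 4.8 mm detector grid.
#'
#' @param n_angles Number of projection angles.
#' @param arc Orbit arc in degrees.
#' @param time_per_projection_s Dwell time per angle, seconds.
#' @param detector_shape Detector pixels (u, v); defaults to the phantom
#'   grid's (nx, nz) when used.
#' @param pixel_spacing_mm Detector pixel pitch, mm (must equal the volume's
#'   in-plane spacing for the parallel-beam model used here).
#' @param orbit_radius_mm Nominal orbit radius, mm (bookkeeping only for the
#'   distance-independent response model).
#' @return An `acquisition_protocol` object.
#' @export
acquisition_protocol <- function(n_angles = 120L, arc = 360,
                                 time_per_projection_s = 15,
                                 detector_shape = NULL,
                                 pixel_spacing_mm = 4.8,
                                 orbit_radius_mm = 250) {
  stopifnot(n_angles >= 1, arc > 0, time_per_projection_s > 0,
            pixel_spacing_mm > 0)
  structure(list(n_angles = as.integer(n_angles), arc = arc,
                 time_per_projection_s = time_per_projection_s,
                 detector_shape = detector_shape,
                 pixel_spacing_mm = pixel_spacing_mm,
                 orbit_radius_mm = orbit_radius_mm),
            class = "acquisition_protocol")
}

protocol_angles <- function(protocol) {
  protocol$arc / protocol$n_angles * (seq_len(protocol$n_angles) - 1)
}

## bilinear in-plane rotation weights: for each source pixel, the 0-based
## indices (npix x 4, -1 outside) and weights of the four camera-frame
## pixels it deposits onto when the slice is rotated by `angle_deg`; each
## in-bounds source's weights sum to one (mass-preserving push)
make_rotation_weights <- function(nx, ny, angle_deg) {
  th <- angle_deg * pi / 180
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  i <- rep(0:(nx - 1), times = ny)
  j <- rep(0:(ny - 1), each = nx)
  xs <- cos(th) * (i - cx) + sin(th) * (j - cy) + cx
  ys <- -sin(th) * (i - cx) + cos(th) * (j - cy) + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  col_of <- function(xi, yi) {
    out <- xi + yi * nx
    out[xi < 0 | xi >= nx | yi < 0 | yi >= ny] <- -1L
    as.integer(out)
  }
  idx <- cbind(col_of(x0, y0), col_of(x0 + 1, y0),
               col_of(x0, y0 + 1), col_of(x0 + 1, y0 + 1))
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  list(idx = idx, w = w)
}

## rotation weights depend only on slice shape and angle; memoised
.rot_cache <- new.env(parent = emptyenv())

rotation_weights_cached <- function(nx, ny, angles) {
  key <- paste(nx, ny, paste(signif(angles, 10), collapse = ","), sep = "|")
  if (is.null(.rot_cache[[key]])) {
    .rot_cache[[key]] <- lapply(angles, function(a)
      make_rotation_weights(nx, ny, a))
  }
  .rot_cache[[key]]
}

## Precomputed per-angle system model: rotation weights, attenuation
## survival factors (for the given mu and attenuation weight), detector PSF
## blur matrices and the counts scale (time x voxel volume).
system_model <- function(mu, protocol, psf_fwhm_mm = 10, atten_weight = 1) {
  d <- dim(mu$data)
  if (!isTRUE(all.equal(mu$spacing[1], mu$spacing[2])))
    stop("in-plane voxel spacing must be isotropic", call. = FALSE)
  angles <- protocol_angles(protocol)
  rot <- rotation_weights_cached(d[1], d[2], angles)
  dy_cm <- mu$spacing[2] / 10
  mu_vec <- as.numeric(mu$data) * atten_weight
  att <- lapply(rot, function(r) {
    # push-rotate mu into the camera frame, consistently with fp_angle
    mu_rot <- rotate_scatter(mu_vec, r$idx, r$w, d[3])
    atten_factors(mu_rot, dy_cm, d[1], d[2], d[3])
  })
  sig_vox <- fwhm_to_sigma(psf_fwhm_mm)
  Bu <- gauss_conv_matrix(d[1], sig_vox / mu$spacing[1], normalize = "row")
  Bv <- gauss_conv_matrix(d[3], sig_vox / mu$spacing[3], normalize = "row")
  list(dims = d, angles = angles, rot = rot, att = att, Bu = Bu, Bv = Bv,
       scale = protocol$time_per_projection_s * prod(mu$spacing) / 1000,
       spacing = mu$spacing, origin = mu$origin)
}

## forward project a concentration array (Bq/ml) through a system model;
## returns expected counts (nx x nz x n_angles) at unit sensitivity times
## `sensitivity` [counts per Bq s]
forward_project_model <- function(model, conc, sensitivity = 1) {
  d <- model$dims
  v <- as.numeric(conc)
  out <- array(0, c(d[1], d[3], length(model$angles)))
  for (a in seq_along(model$angles)) {
    r <- model$rot[[a]]
    det <- fp_angle(v, r$idx, r$w, model$att[[a]], d[1], d[2], d[3])
    out[, , a] <- model$Bu %*% det %*% model$Bv
  }
  out * (sensitivity * model$scale)
}

## exact adjoint of forward_project_model (at the same sensitivity)
backproject_model <- function(model, stack, sensitivity = 1) {
  d <- model$dims
  acc <- numeric(prod(d))
  for (a in seq_along(model$angles)) {
    r <- model$rot[[a]]
    det <- model$Bu %*% stack[, , a] %*% model$Bv
    acc <- acc + bp_angle(det, r$idx, r$w, model$att[[a]], d[1], d[2], d[3])
  }
  array(acc * (sensitivity * model$scale), d)
}

#' Attenuated forward projection
#'
#' Projects an activity concentration volume into parallel-beam expected
#' counts at each protocol angle: line integrals of activity weighted by the
#' photon survival probability `exp(-integral of mu)` from the emission
#' voxel to the detector, convolved with a Gaussian detector response.
#' Expected counts are linear in activity and proportional to the dwell
#' time and the detector sensitivity.
#'
#' @param activity `voxel_volume` of activity concentration, Bq/ml.
#' @param mu `voxel_volume` of linear attenuation, 1/cm, on the same grid.
#' @param protocol An [acquisition_protocol()].
#' @param psf_fwhm_mm Detector response FWHM in mm (0 disables blurring).
#' @param sensitivity Detector sensitivity, counts per (Bq s).
#' @return A numeric array `(n_u, n_v, n_angles)` of expected counts, with
#'   attribute `angles` (degrees).
#' @export
attenuated_forward_project <- function(activity, mu, protocol,
                                       psf_fwhm_mm = 10, sensitivity = 1) {
  stopifnot_same_grid(activity, mu, "activity and mu")
  model <- system_model(mu, protocol, psf_fwhm_mm)
  out <- forward_project_model(model, activity$data, sensitivity)
  attr(out, "angles") <- model$angles
  out
}
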