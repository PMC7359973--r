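#' Phantom specification
#'
#' Describes a digital dual-isotope phantom: a body of soft tissue containing
#' a liver with one or more tumours, and two lungs, on a regular voxel grid.
#' Ho-166 microsphere activity is distributed over the whole liver with a
#' tumour-to-normal concentration ratio; Tc-99m colloid activity is confined
#' to the healthy liver (Kupffer-cell uptake is absent in tumour tissue).
#' The defaults emulate the clinical imaging condition: about 250 MBq of
#' Ho-166 in the field of view at scan time and 50 MBq of Tc-99m colloid,
#' a 5:1 activity ratio.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param spacing Voxel spacing in mm (scalar or length-3).
#' @param organs List of organs; each a list with `name` (one of `"body"`,
#'   `"liver"`, `"tumor"`, `"lung"`), `center` (mm) and `radii` (mm) of an
#'   ellipsoid. Painted in body, lung, liver, tumor order so that the liver
#'   displaces lung overlap and tumours are clipped to the liver.
#' @param ho_total_activity_mbq Total Ho-166 activity in the liver, MBq.
#' @param tc_total_activity_mbq Total Tc-99m activity in the healthy liver, MBq.
#' @param tumor_to_normal_uptake_ratio Ho-166 concentration ratio
#'   tumour : normal liver (dimensionless, > 0).
#' @param background_fraction Fraction of `ho_total_activity_mbq` placed
#'   uniformly in non-liver body tissue (default 0: all activity in-liver).
#' @param mu_soft_81,mu_soft_140 Linear attenuation of soft tissue at 81 and
#'   140 keV, 1/cm.
#' @param lung_mu_fraction Lung attenuation relative to soft tissue.
#' @param liver_density,lung_density Mass densities, g/ml.
#' @param seed Integer seed (reserved for randomised organ variants;
#'   voxelisation itself is deterministic).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         spacing = 4.8,
                         organs = default_organs(),
                         ho_total_activity_mbq = 250,
                         tc_total_activity_mbq = 50,
                         tumor_to_normal_uptake_ratio = 4,
                         background_fraction = 0,
                         mu_soft_81 = 0.18,
                         mu_soft_140 = 0.155,
                         lung_mu_fraction = 0.3,
                         liver_density = 1.06,
                         lung_density = 0.3,
                         seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (ho_total_activity_mbq < 0 || tc_total_activity_mbq < 0)
    stop("activities must be non-negative", call. = FALSE)
  if (tumor_to_normal_uptake_ratio <= 0)
    stop("tumor_to_normal_uptake_ratio must be > 0", call. = FALSE)
  fov <- (grid_shape - 1) * spacing
  for (org in organs) {
    lo <- org$center - org$radii
    hi <- org$center + org$radii
    if (any(lo < -spacing) || any(hi > fov + spacing))
      stop("organ '", org$name, "' extends outside the grid", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 organs = organs,
                 ho_total_activity_mbq = ho_total_activity_mbq,
                 tc_total_activity_mbq = tc_total_activity_mbq,
                 tumor_to_normal_uptake_ratio = tumor_to_normal_uptake_ratio,
                 background_fraction = background_fraction,
                 mu_soft_81 = mu_soft_81, mu_soft_140 = mu_soft_140,
                 lung_mu_fraction = lung_mu_fraction,
                 liver_density = liver_density, lung_density = lung_density,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_organs <- function() {
  list(
    list(name = "body",  center = c(151.2, 151.2, 112.8), radii = c(140, 100, 108)),
    list(name = "lung",  center = c(90, 115, 165),  radii = c(52, 50, 48)),
    list(name = "lung",  center = c(212, 115, 165), radii = c(52, 50, 48)),
    list(name = "liver", center = c(100, 170, 80),  radii = c(85, 60, 55)),
    list(name = "tumor", center = c(80, 160, 70),   radii = c(22, 20, 20))
  )
}

## organ label codes used throughout
LBL <- c(air = 0L, body = 1L, liver = 2L, tumor = 3L, lung = 4L)

ellipsoid_mask <- function(grid_shape, spacing, center, radii) {
  d <- grid_shape
  x <- ((seq_len(d[1]) - 1) * spacing[1] - center[1]) / radii[1]
  y <- ((seq_len(d[2]) - 1) * spacing[2] - center[2]) / radii[2]
  z <- ((seq_len(d[3]) - 1) * spacing[3] - center[3]) / radii[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  r2 <= 1
}

#' Build a phantom from its specification
#'
#' Voxelises the organ ellipsoids into a label map and fills per-voxel
#' activity concentrations (Bq/ml), attenuation maps at 81 and 140 keV
#' (1/cm) and a mass-density map (g/ml). Activity concentrations are chosen
#' so that the voxel-integrated totals reproduce the prescribed MBq exactly
#' on the voxelised organs; Tc-99m is uniform over healthy liver only and is
#' exactly zero in tumour voxels.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` object: a list of `voxel_volume`s (`labels`,
#'   `ho_activity`, `tc_activity`, `mu_81`, `mu_140`, `density`) plus the spec.
#' @export
build_phantom <- function(spec) {
  d <- spec$grid_shape
  labels <- array(LBL[["air"]], d)
  paint_order <- c("body", "lung", "liver", "tumor")
  body <- NULL
  for (nm in paint_order) {
    for (org in spec$organs) {
      if (org$name != nm) next
      m <- ellipsoid_mask(d, spec$spacing, org$center, org$radii)
      if (nm == "body") {
        body <- m
        labels[m] <- LBL[["body"]]
      } else {
        m <- m & body
        if (nm == "tumor") {
          # tumours only exist inside the liver
          m <- m & (labels == LBL[["liver"]])
        }
        labels[m] <- LBL[[nm]]
      }
    }
  }
  if (is.null(body)) stop("spec contains no body organ", call. = FALSE)

  vvol_ml <- prod(spec$spacing) / 1000
  liver_all <- labels == LBL[["liver"]] | labels == LBL[["tumor"]]
  tumor <- labels == LBL[["tumor"]]
  healthy <- labels == LBL[["liver"]]
  bg <- labels == LBL[["body"]]

  ho <- array(0, d)
  n_h <- sum(healthy); n_t <- sum(tumor); n_b <- sum(bg)
  r <- spec$tumor_to_normal_uptake_ratio
  in_liver <- spec$ho_total_activity_mbq * (1 - spec$background_fraction)
  if (in_liver > 0 && (n_h + n_t) > 0) {
    c_norm <- in_liver * 1e6 / ((n_h + r * n_t) * vvol_ml)  # Bq/ml
    ho[healthy] <- c_norm
    ho[tumor] <- r * c_norm
  }
  if (spec$background_fraction > 0 && n_b > 0) {
    ho[bg] <- spec$ho_total_activity_mbq * spec$background_fraction * 1e6 /
      (n_b * vvol_ml)
  }

  tc <- array(0, d)
  if (spec$tc_total_activity_mbq > 0 && n_h > 0) {
    tc[healthy] <- spec$tc_total_activity_mbq * 1e6 / (n_h * vvol_ml)
  }

  mu81 <- array(0, d)
  mu81[labels >= LBL[["body"]]] <- spec$mu_soft_81
  mu81[labels == LBL[["lung"]]] <- spec$mu_soft_81 * spec$lung_mu_fraction
  mu140 <- array(0, d)
  mu140[labels >= LBL[["body"]]] <- spec$mu_soft_140
  mu140[labels == LBL[["lung"]]] <- spec$mu_soft_140 * spec$lung_mu_fraction

  dens <- array(0, d)
  dens[labels >= LBL[["body"]]] <- spec$liver_density
  dens[labels == LBL[["lung"]]] <- spec$lung_density

  vv <- function(a, units) voxel_volume(a, spec$spacing, units = units)
  structure(list(labels = vv(labels, "label"),
                 ho_activity = vv(ho, "Bq/ml"),
                 tc_activity = vv(tc, "Bq/ml"),
                 mu_81 = vv(mu81, "1/cm"),
                 mu_140 = vv(mu140, "1/cm"),
                 density = vv(dens, "g/ml"),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$labels$data)
  cat(sprintf("<phantom> %d x %d x %d @ %s mm\n", d[1], d[2], d[3],
              paste(signif(x$labels$spacing, 3), collapse = "x")))
  cat(sprintf("  Ho-166: %.2f MBq, Tc-99m: %.2f MBq\n",
              total_activity_mbq(x$ho_activity), total_activity_mbq(x$tc_activity)))
  invisible(x)
}

#' Organ masks from a phantom
#'
#' @param phantom A `phantom`.
#' @param organ One of `"body"`, `"liver"` (includes tumour), `"healthy"`
#'   (liver minus tumour), `"tumor"`, `"lung"`.
#' @return A logical array.
#' @export
organ_mask <- function(phantom, organ = c("liver", "healthy", "tumor", "lung", "body")) {
  organ <- match.arg(organ)
  l <- phantom$labels$data
  switch(organ,
         body = l >= LBL[["body"]],
         liver = l == LBL[["liver"]] | l == LBL[["tumor"]],
         healthy = l == LBL[["liver"]],
         tumor = l == LBL[["tumor"]],
         lung = l == LBL[["lung"]])
}

#' Ground-truth absorbed dose map
#'
#' Applies the local-deposition beta dose model to the phantom's noiseless
#' Ho-166 activity, rescaled so the field-of-view total equals the
#' administered activity. This is the recovery target against which
#' reconstructed doses are judged.
#'
#' @param phantom A `phantom`.
#' @param administered_activity_mbq Administered Ho-166 activity in MBq.
#' @param model A [dose_model()].
#' @return A `voxel_volume` of absorbed dose in Gy.
#' @export
true_dose_map <- function(phantom, administered_activity_mbq,
                          model = dose_model()) {
  if (administered_activity_mbq < 0)
    stop("administered activity must be non-negative", call. = FALSE)
  act <- phantom$ho_activity
  tot <- total_activity_mbq(act)
  if (tot > 0) {
    act <- with_data(act, act$data * administered_activity_mbq / tot)
  } else if (administered_activity_mbq == 0) {
    # zero-activity phantom: dose is identically zero
  }
  dose_map(act, phantom$density, model)
}

#' Apply a rigid motion to a whole phantom
#'
#' Resamples every phantom volume consistently: labels by nearest-neighbour,
#' continuous volumes by trilinear interpolation. The identity transform
#' returns the phantom unchanged (bitwise).
#'
#' @param phantom A `phantom`.
#' @param t A [rigid_transform()].
#' @return A `phantom` in the transformed pose.
#' @export
apply_rigid_motion <- function(phantom, t) {
  if (all(t$translation == 0) && all(t$rotation == 0)) return(phantom)
  fov <- (dim(phantom$labels$data) - 1) * phantom$labels$spacing
  if (any(abs(t$translation) > 0.25 * fov))
    warning("large translation: body may leave the grid")
  out <- phantom
  out$labels <- resample_into(phantom$labels, phantom$labels, t, "nearest")
  for (nm in c("ho_activity", "tc_activity", "mu_81", "mu_140", "density")) {
    out[[nm]] <- resample_into(phantom[[nm]], phantom[[nm]], t, "trilinear")
  }
  out
}
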