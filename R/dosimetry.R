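#' Holmium-166 beta dose model
#'
#' Local-deposition absorbed-dose model for Ho-166 microspheres: assuming
#' the microspheres stay lodged until the activity has fully decayed, each
#' MBq of initial Ho-166 deposits 15.87 mJ through its beta emissions
#' (96% of the emitted energy; the gamma contribution is ignored since its
#' long range dilutes it far below the beta dose). The mean beta range
#' (2.5 mm) is below the 4.8 mm voxel size, so all energy is absorbed in
#' the emitting voxel:
#'
#' `Dose [Gy] = 15.87 [mJ/MBq] * (concentration [Bq/ml] * 1e-6) / density [g/ml]`
#'
#' @param energy_per_activity_mj_mbq Deposited beta energy per unit initial
#'   activity, mJ/MBq.
#' @param liver_density_g_ml Soft-tissue/liver density, g/ml.
#' @param lung_density_g_ml Lung density, g/ml.
#' @return A `dose_model`.
#' @export
dose_model <- function(energy_per_activity_mj_mbq = 15.87,
                       liver_density_g_ml = 1.06,
                       lung_density_g_ml = 0.3) {
  stopifnot(energy_per_activity_mj_mbq > 0, liver_density_g_ml > 0,
            lung_density_g_ml > 0)
  structure(list(energy_per_activity_mj_mbq = energy_per_activity_mj_mbq,
                 liver_density_g_ml = liver_density_g_ml,
                 lung_density_g_ml = lung_density_g_ml),
            class = "dose_model")
}

#' Rescale a reconstruction to the administered activity
#'
#' Scales a reconstructed volume so that its voxel-integrated total equals
#' the administered activity, giving comparable Bq/ml units across
#' acquisitions under the assumption that all administered activity lies in
#' the reconstructed field of view.
#'
#' @param recon A `recon_volume` or `voxel_volume`.
#' @param administered_mbq Administered activity, MBq.
#' @return A `voxel_volume` in Bq/ml integrating exactly to
#'   `administered_mbq`.
#' @export
rescale_to_administered <- function(recon, administered_mbq) {
  vol <- if (inherits(recon, "recon_volume")) recon$values else recon
  if (administered_mbq <= 0) stop("administered activity must be > 0", call. = FALSE)
  tot <- total_activity_mbq(vol)
  if (tot <= 0) stop("reconstruction has zero total activity", call. = FALSE)
  with_data(vol, vol$data * administered_mbq / tot, units = "Bq/ml")
}

#' Voxelwise absorbed-dose map
#'
#' Applies the local-deposition dose equation voxel by voxel. Voxels with
#' zero activity get zero dose; nonzero activity at zero density is an
#' error.
#'
#' @param activity `voxel_volume` of activity concentration, Bq/ml.
#' @param density `voxel_volume` of mass density, g/ml.
#' @param model A [dose_model()].
#' @return A `voxel_volume` of absorbed dose in Gy.
#' @export
dose_map <- function(activity, density, model = dose_model()) {
  stopifnot_same_grid(activity, density, "activity and density")
  act <- activity$data
  den <- density$data
  if (any(act > 0 & den <= 0))
    stop("nonzero activity at zero density", call. = FALSE)
  dose <- array(0, dim(act))
  nz <- act > 0
  dose[nz] <- model$energy_per_activity_mj_mbq * (act[nz] * 1e-6) / den[nz]
  with_data(activity, dose, units = "Gy")
}

#' Volumes of interest
#'
#' A VOI is a binary voxel mask with a name and a derived volume in ml.
#'
#' @param mask Logical (or 0/1) 3D array, or a `voxel_volume` of the same.
#' @param name VOI name (`"HEALTHY"`, `"TUMOR"`, `"LUNGS"`, `"LIVER"` or
#'   custom).
#' @param spacing,origin Grid geometry when `mask` is a bare array.
#' @return A `voi_mask`.
#' @export
voi_mask <- function(mask, name = "custom", spacing = c(4.8, 4.8, 4.8),
                     origin = c(0, 0, 0)) {
  if (inherits(mask, "voxel_volume")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- mask$data
  }
  mask <- array(as.logical(mask), dim(mask))
  structure(list(mask = mask, name = name, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 volume_ml = sum(mask) * prod(spacing) / 1000),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s: %d voxels, %.2f ml\n", x$name, sum(x$mask),
              x$volume_ml))
  invisible(x)
}

#' Analytic ellipsoidal VOI
#'
#' Voxelises an axis-aligned ellipsoid on the given grid; the voxelised
#' volume agrees with `4/3 pi abc` to within a voxel shell.
#'
#' @param center_mm,radii_mm Ellipsoid centre and semi-axes in mm.
#' @param grid A `voxel_volume` defining the grid.
#' @param name VOI name.
#' @return A `voi_mask`.
#' @export
make_ellipsoid_voi <- function(center_mm, radii_mm, grid, name = "HEALTHY") {
  if (any(radii_mm <= 0)) {
    m <- array(FALSE, dim(grid$data))
  } else {
    m <- ellipsoid_mask(dim(grid$data), grid$spacing,
                        center_mm - grid$origin, radii_mm)
  }
  voi_mask(m, name, grid$spacing, grid$origin)
}

## largest 6-connected component by iterative label propagation
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  shift <- function(a, ax, by) {
    out <- array(0, dim(a))
    idx_src <- lapply(dim(a), seq_len)
    idx_dst <- idx_src
    n <- dim(a)[ax]
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  repeat {
    new <- lab
    for (ax in 1:3) for (by in c(1, -1)) {
      nb <- shift(lab, ax, by)
      new <- pmax(new, nb * (mask & nb > 0))
    }
    if (all(new == lab)) break
    lab <- new
  }
  ids <- lab[mask]
  if (length(ids) == 0) return(mask)
  big <- as.numeric(names(which.max(table(ids))))
  lab == big
}

#' Automatic healthy-liver segmentation from the Tc-99m image
#'
#' Tc-99m colloid is taken up by Kupffer cells, present in healthy liver
#' parenchyma and absent in tumours, so thresholding the reconstructed
#' Tc-99m image delineates the healthy liver automatically. Voxels above
#' `threshold_fraction` of the image maximum are kept and reduced to the
#' largest 6-connected component.
#'
#' @param tc_recon `recon_volume` or `voxel_volume` of the Tc-99m image.
#' @param threshold_fraction Fraction of the maximum (default 0.4).
#' @return A `voi_mask` named `"HEALTHY"`.
#' @export
segment_healthy_from_tc <- function(tc_recon, threshold_fraction = 0.4) {
  vol <- if (inherits(tc_recon, "recon_volume")) tc_recon$values else tc_recon
  thr <- threshold_fraction * max(vol$data)
  m <- vol$data > thr
  if (!any(m)) {
    warning("threshold above image maximum: empty healthy mask")
    return(voi_mask(m, "HEALTHY", vol$spacing, vol$origin))
  }
  voi_mask(largest_component(m), "HEALTHY", vol$spacing, vol$origin)
}

#' Tumour segmentation from the Ho-166 image
#'
#' Tumours present focused Ho-166 uptake; voxels above
#' `threshold_fraction` of the maximum, excluding the healthy-liver mask,
#' form the tumour VOI (largest connected component).
#'
#' @param ho_recon `recon_volume` or `voxel_volume` of the Ho-166 image.
#' @param healthy_mask A `voi_mask` (or logical array) to exclude.
#' @param threshold_fraction Fraction of the maximum (default 0.4).
#' @return A `voi_mask` named `"TUMOR"`.
#' @export
segment_tumor_from_ho <- function(ho_recon, healthy_mask = NULL,
                                  threshold_fraction = 0.4) {
  vol <- if (inherits(ho_recon, "recon_volume")) ho_recon$values else ho_recon
  m <- vol$data > threshold_fraction * max(vol$data)
  if (!is.null(healthy_mask)) {
    hm <- if (inherits(healthy_mask, "voi_mask")) healthy_mask$mask else healthy_mask
    m <- m & !hm
  }
  if (any(m)) m <- largest_component(m)
  voi_mask(m, "TUMOR", vol$spacing, vol$origin)
}

## binary erosion by a Euclidean ball, via FFT convolution with the
## complement: a voxel survives when no background voxel lies within r
erode_ball <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  d <- dim(mask)
  rv <- ceiling(radius_mm / spacing)
  off <- lapply(1:3, function(ax) (-rv[ax]):rv[ax])
  kern <- array(0, 2 * rv + 1)
  g <- expand.grid(x = off[[1]] * spacing[1], y = off[[2]] * spacing[2],
                   z = off[[3]] * spacing[3])
  kern[] <- as.numeric(sqrt(g$x^2 + g$y^2 + g$z^2) <= radius_mm)
  pd <- d + dim(kern) - 1
  padded <- array(0, pd)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- !mask
  kp <- array(0, pd)
  kp[seq_len(dim(kern)[1]), seq_len(dim(kern)[2]), seq_len(dim(kern)[3])] <- kern
  conv <- Re(stats::fft(stats::fft(padded) * stats::fft(kp), inverse = TRUE)) /
    prod(pd)
  ctr <- rv  # kernel centre offset
  hits <- conv[ctr[1] + seq_len(d[1]), ctr[2] + seq_len(d[2]),
               ctr[3] + seq_len(d[3])]
  mask & (hits < 0.5)
}

#' Lung mask from the attenuation map
#'
#' Thresholds the attenuation map to the lung band (low but nonzero mu
#' inside the body), then shrinks the delineation by a Euclidean ball —
#' by default 2 cm — to avoid partial-volume contamination and liver
#' scatter near the edges.
#'
#' @param mu_map `voxel_volume` of attenuation (1/cm).
#' @param shrink_cm Erosion radius in cm (default 2).
#' @param mu_soft Soft-tissue reference mu; defaults to the map maximum.
#' @param band Lung band as fractions of `mu_soft` (default 5% to 60%).
#' @return A `voi_mask` named `"LUNGS"`.
#' @export
lung_mask <- function(mu_map, shrink_cm = 2, mu_soft = NULL,
                      band = c(0.05, 0.60)) {
  if (is.null(mu_soft)) mu_soft <- max(mu_map$data)
  m <- mu_map$data > band[1] * mu_soft & mu_map$data < band[2] * mu_soft
  m <- erode_ball(m, shrink_cm * 10, mu_map$spacing)
  if (!any(m) && shrink_cm > 0)
    warning("lung mask empty after shrinking by ", shrink_cm, " cm")
  voi_mask(m, "LUNGS", mu_map$spacing, mu_map$origin)
}

#' Minimum-volume rule for VOIs
#'
#' Small VOIs make activity recovery unreliable (partial-volume and
#' registration errors dominate); VOIs below the minimum volume are
#' rejected from dose reporting.
#'
#' @param voi A `voi_mask`.
#' @param min_ml Minimum volume in ml (default 25).
#' @return A list with `accepted` (logical) and `reason` (string or `NA`).
#' @export
enforce_min_volume <- function(voi, min_ml = 25) {
  if (voi$volume_ml >= min_ml) {
    list(accepted = TRUE, reason = NA_character_)
  } else {
    list(accepted = FALSE,
         reason = sprintf("%s volume %.2f ml below minimum %.0f ml",
                          voi$name, voi$volume_ml, min_ml))
  }
}

#' Mean absorbed dose in a VOI
#'
#' @param dose `voxel_volume` of dose in Gy.
#' @param voi A `voi_mask` (or logical array).
#' @return Mean dose in Gy over the VOI voxels.
#' @export
mean_voi_dose <- function(dose, voi) {
  m <- if (inherits(voi, "voi_mask")) voi$mask else voi
  if (!any(m)) stop("empty VOI", call. = FALSE)
  mean(dose$data[m])
}

#' Per-VOI dose report
#'
#' Computes the mean absorbed dose in each VOI passing the minimum-volume
#' rule and returns one tibble row per VOI.
#'
#' @param dose `voxel_volume` of dose in Gy.
#' @param vois A list of `voi_mask`s.
#' @param administered_mbq Administered activity (carried into the report).
#' @param min_ml Minimum VOI volume in ml.
#' @return A tibble with columns `voi`, `volume_ml`, `mean_dose_gy`,
#'   `accepted`, `reason`, `administered_mbq`.
#' @export
dose_report <- function(dose, vois, administered_mbq = NA_real_, min_ml = 25) {
  purrr::map_dfr(vois, function(v) {
    chk <- enforce_min_volume(v, min_ml)
    tibble::tibble(
      voi = v$name,
      volume_ml = v$volume_ml,
      mean_dose_gy = if (chk$accepted) mean_voi_dose(dose, v) else NA_real_,
      accepted = chk$accepted,
      reason = chk$reason,
      administered_mbq = administered_mbq
    )
  })
}

#' Dice overlap of two masks
#'
#' @param a,b `voi_mask`s or logical arrays.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  am <- if (inherits(a, "voi_mask")) a$mask else a
  bm <- if (inherits(b, "voi_mask")) b$mask else b
  s <- sum(am) + sum(bm)
  if (s == 0) return(1)
  2 * sum(am & bm) / s
}
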