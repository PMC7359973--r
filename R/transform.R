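#' Rigid transforms
#'
#' A rigid-body transform parameterised by a translation (mm) and rotation
#' angles (degrees) applied about the volume centre in x, then y, then z
#' order. The transform maps points from the moving frame into the fixed
#' frame; the identity has all-zero fields.
#'
#' @param translation Length-3 translation in mm.
#' @param rotation Length-3 rotation in degrees about the x, y and z axes.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, r = (%s) deg\n",
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$rotation, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix_xyz <- function(rot_deg) {
  r <- rot_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3, 3)
  Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3, 3)
  Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Invert or compose rigid transforms
#'
#' @param t,t1,t2 `rigid_transform` objects. `compose_transforms(t1, t2)`
#'   returns the transform equivalent to applying `t2` first, then `t1`.
#'   Because the x-y-z Euler parameterisation is not closed under
#'   composition, the composed rotation is recovered from the combined
#'   rotation matrix.
#' @return A `rigid_transform`.
#' @export
invert_transform <- function(t) {
  R <- rotation_matrix_xyz(t$rotation)
  rigid_from_matrix(t(R), -as.numeric(t(R) %*% t$translation))
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(t1, t2) {
  R1 <- rotation_matrix_xyz(t1$rotation)
  R2 <- rotation_matrix_xyz(t2$rotation)
  rigid_from_matrix(R1 %*% R2, as.numeric(R1 %*% t2$translation) + t1$translation)
}

## recover x->y->z Euler angles (degrees) from a rotation matrix
rigid_from_matrix <- function(R, tr) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  rigid_transform(tr, c(rx, ry, rz) * 180 / pi)
}

transform_norm <- function(t) {
  sqrt(sum(t$translation^2) + sum(t$rotation^2))
}

grid_center_mm <- function(vol) {
  (dim(vol$data) - 1) / 2 * vol$spacing + vol$origin
}

#' Resample a volume through a rigid transform
#'
#' Maps `moving` into the grid of `fixed_grid` under transform `t` (moving
#' frame to fixed frame). Each fixed-grid voxel is pulled from the moving
#' volume at the inverse-transformed location; continuous volumes use
#' trilinear interpolation and label masks nearest-neighbour. Voxels mapped
#' from outside the moving volume are zero.
#'
#' @param fixed_grid A `voxel_volume` defining the target grid.
#' @param moving The `voxel_volume` to resample.
#' @param t A `rigid_transform` mapping moving-frame points into the fixed
#'   frame.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A `voxel_volume` on the fixed grid.
#' @export
resample_into <- function(fixed_grid, moving, t = rigid_transform(),
                          interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(fixed_grid$data)
  dm <- dim(moving$data)
  # world coordinates of fixed voxels
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  W <- cbind((ix - 1) * fixed_grid$spacing[1] + fixed_grid$origin[1],
             (iy - 1) * fixed_grid$spacing[2] + fixed_grid$origin[2],
             (iz - 1) * fixed_grid$spacing[3] + fixed_grid$origin[3])
  # inverse transform: rotation about the moving volume's centre
  R <- rotation_matrix_xyz(t$rotation)
  ctr <- grid_center_mm(moving)
  P <- sweep(W, 2, t$translation + ctr) %*% R  # == t(Rinv %*% t(w - tr - c))
  P <- sweep(P, 2, ctr, "+")
  # continuous (1-based) voxel coordinates in moving frame
  cx <- (P[, 1] - moving$origin[1]) / moving$spacing[1] + 1
  cy <- (P[, 2] - moving$origin[2]) / moving$spacing[2] + 1
  cz <- (P[, 3] - moving$origin[3]) / moving$spacing[3] + 1
  # snap coordinates that are integer up to rounding noise, so grid-aligned
  # transforms move voxels exactly instead of leaking ~1e-16 weights
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  cx <- snap(cx); cy <- snap(cy); cz <- snap(cz)
  out <- numeric(length(cx))
  if (interpolation == "nearest") {
    rx <- round(cx); ry <- round(cy); rz <- round(cz)
    ok <- rx >= 1 & rx <= dm[1] & ry >= 1 & ry <= dm[2] & rz >= 1 & rz <= dm[3]
    lin <- rx[ok] + (ry[ok] - 1) * dm[1] + (rz[ok] - 1) * dm[1] * dm[2]
    out[ok] <- moving$data[lin]
    if (is.integer(moving$data)) storage.mode(out) <- "integer"
  } else {
    x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
    fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
    acc <- numeric(length(cx))
    for (dz in 0:1) for (dyy in 0:1) for (dxx in 0:1) {
      xi <- x0 + dxx; yi <- y0 + dyy; zi <- z0 + dz
      wgt <- (if (dxx) fx else 1 - fx) * (if (dyy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
      ok <- xi >= 1 & xi <= dm[1] & yi >= 1 & yi <= dm[2] & zi >= 1 & zi <= dm[3] &
        wgt > 0
      if (any(ok)) {
        lin <- xi[ok] + (yi[ok] - 1) * dm[1] + (zi[ok] - 1) * dm[1] * dm[2]
        acc[ok] <- acc[ok] + wgt[ok] * moving$data[lin]
      }
    }
    out <- acc
  }
  voxel_volume(array(out, d), spacing = fixed_grid$spacing,
               origin = fixed_grid$origin, units = moving$units)
}

#' Save and load rigid transforms as JSON
#'
#' @param t A `rigid_transform`.
#' @param path File path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(translation_mm = t$translation,
                            rotation_deg = t$rotation),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$translation_mm, x$rotation_deg)
}
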