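#' Rigid registration of two volumes
#'
#' Aligns `moving` to `fixed` with a rigid-body transform, maximising
#' normalized cross-correlation over the joint body support (normalized
#' mutual information is available via `metric = "nmi"`, but on
#' piecewise-constant attenuation surrogates its 32-bin histogram is too
#' coarse to resolve small rotations, so correlation is the default). The optimiser is fully
#' deterministic: a coarse grid search over integer-voxel translations at
#' zero rotation, followed by local Nelder-Mead refinement of all six
#' parameters. Intended for attenuation-map (CT-surrogate) volumes, which
#' carry the anatomical edges the metric needs.
#'
#' If `fixed` and `moving` are bitwise identical the identity transform is
#' returned immediately.
#'
#' @param fixed,moving `voxel_volume`s on the same grid spacing.
#' @param metric `"ncc"` or `"nmi"`.
#' @param max_translation_vox Half-width of the coarse translation search,
#'   in voxels.
#' @param n_bins Histogram bins per axis for mutual information.
#' @param refine Run the Nelder-Mead refinement after the grid search.
#' @return A `registration_result`: the `rigid_transform` mapping `moving`
#'   into the fixed frame, the final metric value and the number of metric
#'   evaluations.
#' @export
register_rigid <- function(fixed, moving, metric = c("ncc", "nmi"),
                           max_translation_vox = 3L, n_bins = 32L,
                           refine = TRUE) {
  metric <- match.arg(metric)
  if (!isTRUE(all.equal(fixed$spacing, moving$spacing)))
    stop("fixed and moving must share grid spacing", call. = FALSE)
  if (diff(range(fixed$data)) == 0 || diff(range(moving$data)) == 0)
    stop("no gradient information: constant image", call. = FALSE)
  if (identical(dim(fixed$data), dim(moving$data)) &&
      all(fixed$data == moving$data)) {
    return(structure(list(transform = rigid_transform(),
                          final_metric = similarity_metric(fixed$data,
                                                           fixed$data,
                                                           metric, n_bins),
                          n_evaluations = 1L),
                     class = "registration_result"))
  }

  n_eval <- 0L
  eval_at <- function(par) {
    n_eval <<- n_eval + 1L
    t <- rigid_transform(par[1:3], par[4:6])
    warped <- resample_into(fixed, moving, t, "trilinear")
    similarity_metric(fixed$data, warped$data, metric, n_bins)
  }

  # coarse stage 1: integer-voxel translations at zero rotation
  steps <- (-max_translation_vox):max_translation_vox
  best <- c(0, 0, 0, 0, 0, 0)
  best_m <- -Inf
  for (tz in steps) for (ty in steps) for (tx in steps) {
    par <- c(tx * fixed$spacing[1], ty * fixed$spacing[2],
             tz * fixed$spacing[3], 0, 0, 0)
    m <- eval_at(par)
    if (m > best_m) { best_m <- m; best <- par }
  }
  # coarse stage 2: one-dimensional sweeps over small rotations per axis
  for (ax in 1:3) {
    for (ang in seq(-6, 6, by = 1.5)) {
      par <- best
      par[3 + ax] <- ang
      m <- eval_at(par)
      if (m > best_m) { best_m <- m; best <- par }
    }
  }

  if (refine) {
    # scale parameters so one simplex step is ~1 mm / ~1 degree
    opt <- stats::optim(best, function(p) -eval_at(p), method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8,
                                       parscale = rep(1, 6)))
    if (-opt$value >= best_m) { best <- opt$par; best_m <- -opt$value }
  }
  structure(list(transform = rigid_transform(best[1:3], best[4:6]),
                 final_metric = best_m, n_evaluations = n_eval),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n  ")
  print(x$transform)
  cat(sprintf("  metric %.5f after %d evaluations\n",
              x$final_metric, x$n_evaluations))
  invisible(x)
}

## NMI = (H(A) + H(B)) / H(A,B) over the joint support (both voxels > 0);
## NCC over the same support
similarity_metric <- function(a, b, metric, n_bins = 32L) {
  sup <- a > 0 & b > 0
  if (sum(sup) < 10) sup <- rep(TRUE, length(a))
  av <- a[sup]; bv <- b[sup]
  if (metric == "ncc") {
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
    return(stats::cor(av, bv))
  }
  ra <- range(av); rb <- range(bv)
  ia <- pmin(n_bins, 1L + floor((av - ra[1]) / max(ra[2] - ra[1], 1e-12) * n_bins))
  ib <- pmin(n_bins, 1L + floor((bv - rb[1]) / max(rb[2] - rb[1], 1e-12) * n_bins))
  joint <- tabulate(ia + (ib - 1L) * n_bins, nbins = n_bins * n_bins)
  p <- joint / sum(joint)
  pa <- rowSums(matrix(p, n_bins, n_bins))
  pb <- colSums(matrix(p, n_bins, n_bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hj <- ent(p)
  if (hj == 0) return(0)
  (ent(pa) + ent(pb)) / hj
}
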