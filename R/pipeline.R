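#' Experiment configuration
#'
#' Bundles every setting of the paired in-silico experiment: phantom,
#' acquisition protocol, crosstalk model, reconstruction settings, VOI
#' rules and the seed list. Defaults reproduce the study conditions: about
#' 250 MBq Ho-166 in the field of view at scan time with 50 MBq Tc-99m
#' (5:1), 10-iteration 8-subset OSEM with k = 1.15 correction, a 25 ml
#' minimum VOI volume, a 2 cm lung shrink and a ~27.6 ml ellipsoidal
#' healthy-liver VOI.
#'
#' @param spec A [phantom_spec()].
#' @param protocol An [acquisition_protocol()].
#' @param xtalk A [crosstalk_model()].
#' @param windows A window set.
#' @param recon A [recon_config()].
#' @param motion A [rigid_transform()] applied to the phantom before the
#'   dual-isotope acquisition (default: none; the patient stays on the
#'   table).
#' @param seeds Integer vector of replicate seeds.
#' @param administered_mbq Activity the dose maps are rescaled to, MBq
#'   (therapeutic scale by default).
#' @param min_voi_ml Minimum VOI volume for dose reporting, ml.
#' @param lung_shrink_cm Lung delineation shrink, cm.
#' @param healthy_voi_ml Volume of the ellipsoidal healthy-liver VOI, ml.
#' @param register Run rigid registration of the DI arm onto the Ho-only
#'   frame (identity-aligned inputs short-circuit to the identity
#'   transform).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(spec = phantom_spec(),
                              protocol = acquisition_protocol(),
                              xtalk = crosstalk_model(),
                              windows = energy_window_set(),
                              recon = recon_config(),
                              motion = rigid_transform(),
                              seeds = 1:10,
                              administered_mbq = 5757,
                              min_voi_ml = 25,
                              lung_shrink_cm = 2,
                              healthy_voi_ml = 27.57,
                              register = TRUE) {
  if (length(seeds) < 1) stop("need at least one seed", call. = FALSE)
  structure(list(spec = spec, protocol = protocol, xtalk = xtalk,
                 windows = windows, recon = recon, motion = motion,
                 seeds = as.integer(seeds),
                 administered_mbq = administered_mbq,
                 min_voi_ml = min_voi_ml, lung_shrink_cm = lung_shrink_cm,
                 healthy_voi_ml = healthy_voi_ml, register = register),
            class = "experiment_config")
}

## ellipsoidal healthy-liver VOI: sphere of the requested volume at the
## healthy-liver centroid, nudged away from the tumour until disjoint
place_healthy_voi <- function(phantom, volume_ml) {
  healthy <- organ_mask(phantom, "healthy")
  tumor <- organ_mask(phantom, "tumor")
  sp <- phantom$labels$spacing
  idx <- which(healthy, arr.ind = TRUE)
  ctr <- (colMeans(idx) - 1) * sp + phantom$labels$origin
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  t_idx <- which(tumor, arr.ind = TRUE)
  away <- if (nrow(t_idx) > 0) {
    tctr <- (colMeans(t_idx) - 1) * sp + phantom$labels$origin
    dirv <- ctr - tctr
    if (sum(dirv^2) == 0) c(1, 0, 0) else dirv / sqrt(sum(dirv^2))
  } else c(0, 0, 0)
  for (step in 0:20) {
    voi <- make_ellipsoid_voi(ctr + step * sp[1] * away, rep(r, 3),
                              phantom$labels, name = "HEALTHY")
    if (!any(voi$mask & tumor)) return(voi)
  }
  voi
}

zero_tc <- function(phantom) {
  phantom$tc_activity$data[] <- 0
  phantom
}

#' Run the paired Ho-only vs dual-isotope experiment
#'
#' For each seed: build the phantom, simulate the Ho-166-only acquisition
#' and the dual-isotope acquisition (Tc-99m added, optional rigid motion),
#' reconstruct the Ho-166 image from both — with the window-based
#' downscatter correction and, for the comparison arm, without it —
#' register the DI arm back onto the Ho-only frame, construct the VOIs on
#' the Ho-only side (ellipsoidal healthy-liver VOI, the tumour delineation,
#' the shrunken lung mask), rescale to the administered activity, compute
#' dose maps and per-VOI mean doses, and finally the paired agreement
#' statistics across seeds. Fully deterministic given the config.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print per-stage progress to stderr.
#' @return An `experiment_report`: `$doses` (one row per seed x VOI),
#'   `$stats` (per-VOI Bland-Altman / Pearson / t-test for the corrected
#'   arm plus the uncorrected-arm mean difference), and the config.
#' @export
run_paired_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  rows <- list()
  for (seed in cfg$seeds) {
    say("seed %d: phantom", seed)
    spec <- cfg$spec
    spec$seed <- seed
    ph <- build_phantom(spec)
    ph_di_pose <- apply_rigid_motion(ph, cfg$motion)

    say("seed %d: simulate", seed)
    proj_ho <- simulate_acquisition(zero_tc(ph), cfg$protocol, cfg$xtalk,
                                    cfg$windows, seed = seed)
    proj_di <- simulate_acquisition(ph_di_pose, cfg$protocol, cfg$xtalk,
                                    cfg$windows, seed = seed)

    say("seed %d: reconstruct", seed)
    rc <- cfg$recon
    rc$correction <- TRUE
    rec_ho <- reconstruct_ho(proj_ho, ph$mu_81, cfg$protocol, rc)
    rec_di <- reconstruct_ho(proj_di, ph_di_pose$mu_81, cfg$protocol, rc)
    rc_off <- rc
    rc_off$correction <- FALSE
    rec_di_unc <- reconstruct_ho(proj_di, ph_di_pose$mu_81, cfg$protocol, rc_off)

    say("seed %d: register", seed)
    if (cfg$register) {
      reg <- register_rigid(ph$mu_81, ph_di_pose$mu_81)
      tfm <- reg$transform
    } else {
      tfm <- invert_transform(cfg$motion)
    }
    # resampling can smear a voxel shell of activity just outside the
    # patient; clip to the fixed-frame body support (all administered
    # activity is assumed inside the field of view and the patient)
    body <- ph$density$data > 0
    clip <- function(v) { v$data[!body] <- 0; v }
    di_in_ho <- clip(resample_into(ph$mu_81, rec_di$values, tfm, "trilinear"))
    di_unc_in_ho <- clip(resample_into(ph$mu_81, rec_di_unc$values, tfm,
                                       "trilinear"))

    say("seed %d: dosimetry", seed)
    vois <- list(place_healthy_voi(ph, cfg$healthy_voi_ml),
                 voi_mask(organ_mask(ph, "tumor"), "TUMOR",
                          ph$labels$spacing, ph$labels$origin),
                 lung_mask(ph$mu_81, cfg$lung_shrink_cm,
                           mu_soft = spec$mu_soft_81))
    dens <- ph$density
    dmaps <- list(
      true = true_dose_map(ph, cfg$administered_mbq),
      ho = dose_map(rescale_to_administered(rec_ho, cfg$administered_mbq), dens),
      di = dose_map(rescale_to_administered(di_in_ho, cfg$administered_mbq), dens),
      di_unc = dose_map(rescale_to_administered(di_unc_in_ho,
                                                cfg$administered_mbq), dens)
    )
    for (v in vois) {
      chk <- enforce_min_volume(v, cfg$min_voi_ml)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = seed, voi = v$name, volume_ml = v$volume_ml,
        accepted = chk$accepted,
        dose_true = if (chk$accepted) mean_voi_dose(dmaps$true, v) else NA_real_,
        dose_ho = if (chk$accepted) mean_voi_dose(dmaps$ho, v) else NA_real_,
        dose_di = if (chk$accepted) mean_voi_dose(dmaps$di, v) else NA_real_,
        dose_di_uncorrected =
          if (chk$accepted) mean_voi_dose(dmaps$di_unc, v) else NA_real_
      )
    }
  }
  doses <- dplyr::bind_rows(rows)
  doses <- dplyr::filter(doses, .data$accepted)

  stats_tbl <- NULL
  if (length(cfg$seeds) >= 2) {
    stats_tbl <- doses |>
      dplyr::group_by(.data$voi) |>
      dplyr::group_modify(function(df, key) {
        ba <- bland_altman(paired_sample(df$dose_ho, df$dose_di))
        # identical arms (e.g. a zero-Tc control) have no variance to test
        tt <- tryCatch(paired_t_test(paired_sample(df$dose_ho, df$dose_di)),
                       error = function(e) list(statistic = NA_real_,
                                                p_value = NA_real_))
        ba_unc <- bland_altman(paired_sample(df$dose_ho,
                                             df$dose_di_uncorrected))
        dplyr::bind_cols(
          tidy(ba),
          tibble::tibble(pearson_r = tryCatch(
            pearson_r(paired_sample(df$dose_ho, df$dose_di)),
            error = function(e) NA_real_),
                         t_statistic = tt$statistic, p_value = tt$p_value,
                         mean_diff_uncorrected = ba_unc$mean_diff,
                         crp_uncorrected = ba_unc$crp))
      }) |>
      dplyr::ungroup()
  }
  structure(list(doses = doses, stats = stats_tbl, config = cfg),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d seeds, %d VOI rows\n",
              length(unique(x$doses$seed)), nrow(x$doses)))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) {
  if (is.null(x$stats)) tibble::tibble() else x$stats
}

#' @export
glance.experiment_report <- function(x, ...) {
  tibble::tibble(n_seeds = length(unique(x$doses$seed)),
                 n_vois = length(unique(x$doses$voi)),
                 administered_mbq = x$config$administered_mbq)
}

#' Write an experiment report to disk
#'
#' Writes the per-seed dose pairs as CSV, the agreement statistics as JSON
#' and, optionally, one Bland-Altman plot per VOI. Re-running overwrites
#' the same files (idempotent).
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @param plots Also write Bland-Altman PNG files.
#' @return The directory, invisibly.
#' @export
make_report <- function(report, dir, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$doses, file.path(dir, "voi_doses.csv"),
                   row.names = FALSE)
  if (!is.null(report$stats)) {
    jsonlite::write_json(report$stats, file.path(dir, "agreement_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  cfg <- report$config
  prov <- list(seeds = cfg$seeds, administered_mbq = cfg$administered_mbq,
               k_factor = cfg$recon$k_factor,
               n_iterations = cfg$recon$n_iterations,
               n_subsets = cfg$recon$n_subsets,
               min_voi_ml = cfg$min_voi_ml)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (plots && !is.null(report$stats)) {
    for (v in unique(report$doses$voi)) {
      df <- report$doses[report$doses$voi == v, ]
      ba <- bland_altman(paired_sample(df$dose_ho, df$dose_di))
      ggplot2::ggsave(file.path(dir, sprintf("bland_altman_%s.png", v)),
                      autoplot(ba), width = 5, height = 4, dpi = 120)
    }
  }
  invisible(dir)
}

#' @importFrom rlang .data
NULL
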