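# shared fixtures, built once per test run and memoised

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# desk-scale phantom for cheap reconstruction tests
small_organs <- function() {
  list(
    list(name = "body",  center = c(74.4, 74.4, 55.2), radii = c(68, 50, 52)),
    list(name = "lung",  center = c(45, 55, 85),  radii = c(26, 25, 24)),
    list(name = "lung",  center = c(105, 55, 85), radii = c(26, 25, 24)),
    list(name = "liver", center = c(55, 88, 40),  radii = c(40, 30, 28)),
    list(name = "tumor", center = c(45, 82, 35),  radii = c(14, 13, 13))
  )
}

small_spec <- function(organs = small_organs(), ...) {
  phantom_spec(grid_shape = c(32, 32, 24), spacing = 4.8, organs = organs, ...)
}

small_protocol <- function(n_angles = 24L) acquisition_protocol(n_angles = n_angles)

small_phantom <- function() memo("small_phantom", build_phantom(small_spec()))

# full-size phantom and a noiseless dual-isotope acquisition + recons,
# shared by the recovery and segmentation tests
std_phantom <- function() memo("std_phantom", build_phantom(phantom_spec()))

std_proj_noiseless <- function() memo("std_proj_noiseless", {
  simulate_acquisition(std_phantom(), noise = FALSE)
})

std_ho_recon <- function() memo("std_ho_recon", {
  reconstruct_ho(std_proj_noiseless(), std_phantom()$mu_81)
})

std_tc_recon <- function() memo("std_tc_recon", {
  reconstruct_tc(std_proj_noiseless(), std_phantom()$mu_140)
})

no_tc <- function(phantom) {
  phantom$tc_activity$data[] <- 0
  phantom
}
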