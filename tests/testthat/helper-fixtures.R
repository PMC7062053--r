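# Shared fixture builders: small straight-tube geometries and analytic flows.

straight_tube <- function(length = 40, r = 12.5, h = 1.25, n = 9L,
                          circ = 32L) {
  build_tube_geometry(cbind(0, 0, seq(0, length, length.out = n)),
                      radius_profile = r, thickness_profile = h,
                      circumferential_resolution = circ,
                      segment_bounds = c(0, 1), segment_names = "ascending")
}

steady_flow <- function(Q = 100, ...) {
  flow_params(mean_flow = Q, peak_mean_ratio = 1, ...)
}

# core-station filter: drop tube-end stations where the shear stencil
# reaches past the sampled field
core_stations <- function(geometry, margin = 2L) {
  st <- geometry$surface$station
  st > margin & st <= max(st) - margin
}

default_inlet <- function() generate_waveform(flow_params(), n_frames = 100L)

default_windkessel <- function(R = 1.5e8, tau = 1 / 3) {
  windkessel_params(R, tau / R)
}
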