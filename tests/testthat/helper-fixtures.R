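# Shared fixtures built in code: forward-model gated series and tiny
# protocols used across test files.

default_bins <- function(width_ps = 25, max_ps = 4000) {
  edges <- seq(0, max_ps, by = width_ps)
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2)
}

# noise-free gated intensities from the diffusion forward model, for a
# given per-frame absorption trajectory (one channel, one wavelength)
forward_gated <- function(mua_t, props, gates = gate_set(),
                          wavelength = 760, frame_times = seq_along(mua_t) - 1,
                          bin_width = 25) {
  b <- default_bins(bin_width)
  v <- 0.299792458 / props$n_tissue
  mf <- semi_infinite_reflectance(b$centers, props, mua_free = TRUE)
  vals <- array(NA_real_, c(1, 1, 3, length(mua_t)),
                dimnames = list(channel = 1, wavelength = wavelength,
                                gate = 1:3, frame = NULL))
  for (g in 1:3) {
    keep <- b$centers >= gates$starts_ps[g] & b$centers < gates$ends_ps[g]
    vals[1, 1, g, ] <- colSums(mf[keep] *
                                 exp(-v * outer(b$centers[keep], mua_t)))
  }
  structure(list(values = vals, channels = 1L, wavelengths = wavelength,
                 gate_set = gates, frame_times_s = frame_times),
            class = "gated_series")
}

# two-wavelength gated series driven by programmed HbO(t)/HbR trajectories
forward_gated_2wl <- function(hbo_t, hbr, props, ext = extinction_table(),
                              gates = gate_set(),
                              frame_times = seq_along(hbo_t) - 1) {
  stopifnot(length(ext$wavelengths_nm) == 2)
  per_wl <- lapply(1:2, function(wi) {
    mua_t <- ext$matrix[wi, "HbO"] * hbo_t + ext$matrix[wi, "HbR"] * hbr
    forward_gated(mua_t, props, gates, ext$wavelengths_nm[wi], frame_times)
  })
  vals <- array(NA_real_, c(1, 2, 3, length(hbo_t)),
                dimnames = list(channel = 1,
                                wavelength = ext$wavelengths_nm,
                                gate = 1:3, frame = NULL))
  for (wi in 1:2) vals[1, wi, , ] <- per_wl[[wi]]$values[1, 1, , ]
  structure(list(values = vals, channels = 1L,
                 wavelengths = ext$wavelengths_nm, gate_set = gates,
                 frame_times_s = frame_times),
            class = "gated_series")
}

# short protocol for fast pipeline tests
short_protocol <- function() task_protocol(rest_pre_s = 10, task_s = 20,
                                           rest_post_s = 10, fs_hz = 1)

# small HBO_DIRECT cohort spec for fast statistical tests
small_spec <- function(seed, ...) {
  cohort_spec(n_per_group = 6, sessions_per_subject = 1, n_channels = 8,
              corruption_probability = 0, seed = seed, ...)
}
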