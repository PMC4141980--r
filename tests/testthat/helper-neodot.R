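# Shared small fixtures for the unit tests.

# A minimal n-channel line probe with the given source-detector separations.
line_probe <- function(separations_mm, wavelengths = c(780, 850)) {
  n <- length(separations_mm)
  src <- cbind(x = rep(0, n), y = (seq_len(n) - 1) * 10, z = 0)
  det <- cbind(x = separations_mm, y = (seq_len(n) - 1) * 10, z = 0)
  rownames(src) <- paste0("S", seq_len(n))
  rownames(det) <- paste0("D", seq_len(n))
  probe_geometry(src, det,
                 channels = data.frame(source = rownames(src),
                                       detector = rownames(det)),
                 wavelengths = wavelengths)
}

homog_properties <- function(mua = 0.01, musp = 1.0) {
  data.frame(tissue = "homog", wavelength_nm = c(780, 850),
             mua_mm = mua, musp_mm = musp, refractive_index = 1.4)
}

# Coarse homogeneous slab for FEM / Jacobian unit tests (fast, < 2000 nodes).
coarse_slab <- function() {
  make_layer_mesh("slab", layer_thicknesses = c(homog = Inf),
                  slab_dims_mm = c(60, 40, 30),
                  x_breaks = seq(0, 60, by = 5),
                  y_breaks = seq(0, 40, by = 5),
                  z_breaks = c(seq(0, 10, by = 2.5), seq(15, 30, by = 5)),
                  properties = homog_properties())
}

# Single-event global trace from the analytic waveform, as a global_mean()
# style tibble at 10 Hz.
waveform_global <- function(onset_s = 300, duration_s = 900,
                            t_rise_s = 12.5, t_fall_s = 116,
                            t_recover_s = 123, lead = 0) {
  t <- seq(0, duration_s, by = 0.1)
  p <- biphasic_response(onset_s = onset_s, t_rise_s = t_rise_s,
                         t_fall_s = t_fall_s, t_recover_s = t_recover_s,
                         pre_onset_lead_s = lead)
  w <- make_response_waveform(p, t)
  w
}
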