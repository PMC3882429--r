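# minimal event table for hand-built recordings
flash_event <- function(wavelength_nm, strength_ph_um2, t_abs_s,
                        label = "dim") {
  data.frame(wavelength_nm = wavelength_nm,
             strength_ph_um2 = strength_ph_um2,
             t_on_s = t_abs_s, duration_ms = 5, label = label,
             sweep = 1L, t_abs_s = t_abs_s, stringsAsFactors = FALSE)
}

# wrap a bare voltage trace as a recording object
as_recording <- function(t_s, v_mV, events, fs_hz) {
  structure(list(
    t_s = t_s, v_mV = v_mV,
    stim520_ph_um2_s = numeric(length(t_s)),
    stim365_ph_um2_s = numeric(length(t_s)),
    events = events, spec = NULL, fs_hz = fs_hz,
    seed = 0, noise_sd_mV = 0, t_start_min = 0), class = "pr_recording")
}
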