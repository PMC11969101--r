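# Small constructors used across tests.

# A spectrum with arbitrary per-channel fluence on an integer-keV grid.
make_spectrum <- function(fluence, e_min = 10, tube_voltage = e_min + length(fluence),
                          filtration = 0) {
  pcthresh:::new_spectrum(seq(e_min, length.out = length(fluence)),
                          as.double(fluence), tube_voltage, filtration, "test")
}

# A flat spectrum of `value` counts per channel covering [e_min, tube_voltage).
uniform_spectrum <- function(tube_voltage, value = 1, e_min = 10) {
  make_spectrum(rep(value, tube_voltage - e_min), e_min, tube_voltage)
}

# A corrected attenuation-factor stub (for calibration-inversion tests).
corrected_mu <- function(value, bin) {
  structure(list(value = value, bin = bin, corrected = TRUE,
                 rho_t = NA_real_, negative = FALSE, clamped = FALSE),
            class = "pc_mu")
}
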