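# Shared fixtures, all generated in code.

protocol_params <- function() misl_params(alpha = 0.42, r1rho_tissue = 1.72, r1_csf = 0.23)

protocol_t_sat <- 3.725

# saturation times of the shortened trains (seconds)
protocol_t_sat_series <- c(0.5, 1.025, 2, 2.975, 3.725)

# a small bimodal "long-TE" test volume: bright CSF blob in suppressed tissue
bimodal_volume <- function(dims = c(16, 16, 12), csf = 1000, tissue = 50) {
  vol <- array(tissue, dims)
  csf_mask <- array(FALSE, dims)
  csf_mask[6:11, 6:11, 5:8] <- TRUE
  vol[csf_mask] <- csf
  list(volume = vol, csf_mask = csf_mask,
       brain_mask = array(TRUE, dims))
}

quiet_phantom <- function(...) suppressMessages(build_phantom(phantom_spec(...)))
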