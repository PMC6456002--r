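# shared fixtures, built in code at test time

noiseless_acq <- function(...) {
  acquisition_model(bg_cfp = 0, bg_yfp = 0, noise_sd = 0, ...)
}

# a small, fast HeLa-like recording through the glucose-removal protocol
fixture_sim <- local({
  cache <- new.env()
  function(protocol_name = "glucose_removal", arch = archetype("hela_like"),
           dt_out = 2) {
    key <- paste(protocol_name, arch$label, dt_out)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_cell(arch, make_protocol(protocol_name),
                                    dt_out = dt_out)
    cache[[key]]
  }
})

# synthetic ratio trace with a triangular bump of given height on a flat base
bump_trace <- function(n = 300, base = 1, height = 0.3, t_on = 100,
                       t_peak = 150, t_off = 200, normalized = TRUE) {
  time <- seq_len(n) - 1
  up <- pmax(0, pmin((time - t_on) / (t_peak - t_on),
                     (t_off - time) / (t_off - t_peak)))
  ratio <- base + height * up
  structure(data.frame(time = time, ratio = ratio,
                       valid = rep(TRUE, n)),
            cell_id = "bump", compartment = "mito",
            provenance = c("background_subtracted", "ratio_computed",
                           if (normalized) "normalized"),
            normalized = normalized, class = c("ratio_trace", "data.frame"))
}

# plain ratio_trace from vectors (already "processed")
ratio_trace_from <- function(time, ratio, valid = rep(TRUE, length(time)),
                             normalized = FALSE) {
  structure(data.frame(time = time, ratio = ratio, valid = valid),
            cell_id = "manual", compartment = "mito",
            provenance = c("background_subtracted", "ratio_computed",
                           if (normalized) "normalized"),
            normalized = normalized, class = c("ratio_trace", "data.frame"))
}
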