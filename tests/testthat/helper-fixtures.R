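# Shared fixture builders for the test suite.

# Noiseless trace with explicit plateau/baseline geometry.
make_clean_trace <- function(plateau_nm = 90, drift = 0, stiffness = 0.3,
                             sampling_rate = 1000) {
  spec <- trace_gen_spec(sampling_rate = sampling_rate,
                         trap_stiffness = stiffness,
                         true_force = plateau_nm * stiffness,
                         noise_sd = 0, drift_offset = drift)
  gen_tether_trace(spec)$trace
}

# Minimal proteinGroups-style table (one experiment column per condition
# unless E > 1).
make_pg_table <- function(ids, inter, mito, E = 1) {
  stopifnot(length(ids) == length(inter), length(inter) == length(mito))
  tab <- data.frame(ids, ids, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("Protein IDs", "Gene names")
  for (e in seq_len(E)) {
    tab[[paste0("LFQ intensity interphase_", e)]] <- inter
    tab[[paste0("LFQ intensity mitotic_", e)]] <- mito
  }
  tab
}

# Tether measurement rows for QC / summary tests.
make_measurements <- function(forces, cell_id = "c1", phase = "interphase",
                              experiment_id = "e1", qc_flags = "") {
  data.frame(cell_id = cell_id, experiment_id = experiment_id, phase = phase,
             force_pN = forces, baseline_pN = 0,
             plateau_start = 11, plateau_end = 12,
             baseline_start = 12.2, baseline_end = 14,
             qc_flags = qc_flags, stringsAsFactors = FALSE)
}
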