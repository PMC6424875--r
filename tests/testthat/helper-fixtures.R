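# Shared fixture builders; everything is generated in code at test time.

ptblack_circuit <- function() electrode_circuit(R_ct = 10e6, C_dl = 1.44e-9, Z_in = 50e6)
brightpt_circuit <- function() electrode_circuit(R_ct = 10e6, C_dl = 0.077e-9, Z_in = 50e6)

# 2 x 2 electrode block with the neuron's AIS on electrode 1
tiny_scene <- function(q50_pC = 1.5, slope_pC = 0.15, peak_uV = 150, p_max = 1) {
  list(
    geometry = array_geometry(2, 2),
    neuron = synthetic_neuron(c(0, 0), peak_amplitude_uV = peak_uV,
                              q50_pC = q50_pC, slope_pC = slope_pC,
                              p_max = p_max),
    circuit = ptblack_circuit()
  )
}

# Small current-mode session: one biphasic waveform, few amplitudes
tiny_session <- function(seed, amplitudes = c(42, 126, 189), repetitions = 30,
                         scene = tiny_scene(), ...) {
  conds <- current_protocol_conditions(shapes = "biphasic_anodic_cathodic",
                                       durations_us = 20,
                                       amplitudes = amplitudes)
  prot <- randomize_protocol(conds, repetitions, rate = 1, seed = seed)
  simulate_session(prot, scene$neuron, scene$geometry, scene$circuit,
                   seed = seed + 10000, ...)
}

# Ground-truth response counts per condition, ordered by condition_id
gt_counts <- function(session) {
  gt <- session$ground_truth
  vapply(sort(unique(gt$condition_id)),
         function(id) sum(gt$responded[gt$condition_id == id]), 0L)
}

# Small fieldsim domain: 2 x 2 electrodes in a reduced electrolyte block
small_domain <- function(spacing_um = 2.5) {
  build_domain(block_um = c(150, 150, 50), spacing_um = spacing_um,
               n_rows = 2, n_cols = 2)
}
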