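array_name: NSOG
n_receivers: 27
spacing_km: 0.8
gap_after_index: 7
gap_km: 8.0
malaspina_indices: 1-7
gap_mode: add
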