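# Stimulus-run preprocessing (read with read_preprocess_config())
n_discard_volumes: 2
pairwise_average: true
slice_order: none
smoothing_fwhm: 2
highpass_fwhm: 12
highpass_cycles: 9
motion_correction: none
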