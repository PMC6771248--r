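# Default pipeline run: synthetic cohort emulating the pretargeted Lu-177
# experiment, doses scaled to the 40 MBq therapy administration.
synthetic: default
nuclide_name: Lu-177
scheme: trapezoid_tail
decay_correct: true
curve_by: mouse
administered_MBq: 40
out_dir: mirdose_out
seed: 1
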