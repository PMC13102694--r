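# Example pipeline configuration for a 4-day cultured-cell recording with
# one dye switch at day 2. Used as:
#   tapetrace run --in cell.tif --config example_run.yaml --out results/
structural: structural
dyes: [dye1, dye2]
signals: [fos]
nissl: nissl
schedule_times: [2]
fixation: 4
mode: cultured
sampling: cylindrical
seed: 1
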