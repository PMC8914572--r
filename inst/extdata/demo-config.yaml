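# Small demonstration run: simulate a baseline cohort, emulate all four
# target trials at the 1.5 h driving-time threshold, bootstrap 200 CIs and
# render the report tables.  Finishes in a few minutes on one CPU.
scm:
  scenario: baseline
  n_hospitals: 40
  n_surgeons: 80
  n_patients: 2000
trials: [1, 2, 3, 4]
thresholds: [1.5]
bootstrap:
  n_resamples: 200
  cluster_unit: hospital
model:
  interaction: false
seed: 1
output_dir: volemu-demo
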