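# Demo: force-tempered run on the harmonic collective-variable fixture.
#   Rscript inst/cli/forcetemper.R run --config inst/extdata/demo-harmonic.yaml --out out/
system:
  kind: harmonic
  stiffness: 1.0
  center: 0.0
integrator:
  timestep: 0.2
  friction: 0.2
  beta: 1.0
  n_steps: 20000
  seed: 1
fisst:
  f_min: -2.0
  f_max: 2.0
  n_points: 121
  update_interval: 500
output:
  record_every: 1
analysis:
  - type: histogram
    name: hist_f0
    force: 0.0
    n_bins: 50
  - type: force_extension
    name: force_extension
    forces: [-2.0, -1.0, 0.0, 1.0, 2.0]
  - type: reweighted_average
    name: mean_extension_f1
    force: 1.0
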