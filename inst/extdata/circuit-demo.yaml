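# Small demonstration experiment for the command-line wrapper:
#   Rscript inst/cli/dib.R run --config inst/extdata/circuit-demo.yaml \
#       --out /tmp/dib-demo --seed 1
kind: circuit
seed: 1
out_dir: dib-demo-artifact
data:
  n_inputs: 4
  n_gates: 4
model:
  latent_dim: 2
  decoder_hidden: [32, 32]
schedule:
  beta_start: 1.0e-4
  beta_end: 1.0
  n_steps: 1500
eval:
  K: 256
  n_batches: 2
  n_label_samples: 4
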