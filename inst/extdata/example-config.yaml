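# Example run configuration (desk scale).  All keys optional; defaults in
# multishift::load_config().  The CLI's --config flag reads this format.
design:
  m: 4
  M: 400          # tiles per structure; must be a perfect square
  q: 4            # shifting sequence S1 -> ... -> Sq
  pattern_seed: 7
simulation:
  epsilon: 11.5   # bond energy, kT
  mu: -20         # chemical potential, kT
  lambda: 8       # non-reciprocal strength, kT
  sweeps: 3.0e5
  seed_side: 20   # initial seed block edge (here: the full structure)
  sample_every: 500
  rng_seed: 11
experiment:
  replicas: 5
output:
  dir: runs/example
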