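# Reference study conditions: a social-network layer from an Erdos-Renyi
# model embedded into a 50-node Voronoi spatial network, attractiveness
# drawn from Uniform(1, 100) and rescaled. Network A is regenerated per
# realization (no path given). Scale n_realizations up to 1000 to
# reproduce the full experiment.
network_a:
  generator: er
  n: 1000
  p: 0.01
network_b:
  generator: voronoi
  n: 50
attractiveness:
  low: 1
  high: 100
q: [0, 0.5, 1]
n_realizations: 200
seed: 42
ode_step: 0.1
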