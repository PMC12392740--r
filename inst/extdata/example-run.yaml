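# Scaled-down condensate-coupled assembly run (dodecahedron model).
model: dodecahedron
eps_ss: 6
eps_c: 7
N: 120
rho_T: 4.0e-4
V_r: 5.03e-3
dt: 5.0e-3
gamma: 1
T: 1
t_F: 3500
snapshot_every: 350
n_replicates: 5
base_seed: 7007
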