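# Tetrameric sensor population sharing a small finite input pool:
# 20 sensors (80 binding sites) and 224 input molecules, so free-ligand
# depletion is appreciable and simulated exactly.
# The conformational rates are synthetic: only their ratio K = f_L/b_L
# is constrained by the biases, and they are placed geometrically
# (f_L = sqrt(K), b_L = 1/sqrt(K) per second).
K: 100
c: 0.01
"n": 4
N_sensors: 20
L_molecules: 224
f_R: 0.01
b_R: 1
f_T: 0.01
b_T: 100
f_L: 10
b_L: 0.1
topology: L_only
t_max: 20000
seed: 1
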