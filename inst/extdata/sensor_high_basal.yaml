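# Tetrameric sensor population with a high basal activity (K = 2), used
# for noise-curve studies: the variance of the active-sensor count peaks
# where the activity crosses 50%, which lies below the threshold input
# for this parameter set.
# The conformational rates are synthetic (geometric placement around
# 1 s^-1 with ratio K).
K: 2
c: 0.1
"n": 4
N_sensors: 100
L_molecules: 500
f_R: 0.01
b_R: 10
f_T: 0.01
b_T: 100
f_L: 1.4142135623730951
b_L: 0.7071067811865476
topology: L_only
t_max: 400
seed: 1
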