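mu0: 96000
sigma0_sq: 2463931044
tau_sq: 131915692804
N: 4000
rho: 0.2
c1: 5000
c2: 61032
cf: 1000000
theta_a: 24819
conventional_alpha: 0.025
conventional_beta: 0.8
sweep_N: 100,1000,4000,10000,100000,1000000,10000000
sweep_c2: 0,12409,24819,61032,96000,120819
threshold_c2: 61032,0,96000,120819
mc_replicates: 100000
mc_seed: 1
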