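n_per_group: 6
k_mean: 0.09902102579427789
tv0_mean: 200.0
cv0: 0.20000000000000001
cvk: 0.05
sigma: 0.05
tv_max: 3000.0
t_obs: 21.0
schedule:
- 0.0
- 4.0
- 7.0
- 10.0
- 14.0
- 18.0
- 21.0
arms:
  C:
    arm: C
    tgi21: 0.0
    t_ki: 0.0
    p_rt: 0.0
    t_ir: 0.0
  A:
    arm: A
    tgi21: 0.5
    t_ki: 0.0
    p_rt: 0.0
    t_ir: 0.0
  B:
    arm: B
    tgi21: 0.40000000000000002
    t_ki: 0.0
    p_rt: 0.0
    t_ir: 0.0
  AB:
    arm: AB
    tgi21: 0.84999999999999998
    t_ki: 0.0
    p_rt: 0.0
    t_ir: 0.0
seed: 1.0
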