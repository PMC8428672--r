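# Fitted baseline for the northeast Nigeria snakebite registry.
# All rates are per month (the model's time unit).  Demographic rates are
# derived from life-expectancy arithmetic in days (mu = 1/(life expectancy
# in days); Lambda_H = population * mu_H) and converted with a 365/12-day
# month.
parameters:
  Lambda_H: 40271.66666666667   # 1324 persons/day
  Lambda_S: 0.1925
  mu_H: 1.5337908333333333e-03  # 1/(54.332 y) = 5.0426e-5/day
  mu_S: 6.944125e-03            # 1/(12 y) = 2.283e-4/day
  beta: 0.0742
  epsilon: 0.0051
  theta: 1.7729e-04
  tau: 0.9997
  k: 0.8073
  delta_1: 0.0025
  delta_2: 4.2564e-04
  alpha_1: 0.1215
  alpha_2: 0.1708
  gamma_1: 0.9310
  gamma_2: 0.9310
  sigma_1: 0.9924
  sigma_2: 0.9924
  rho_1: 0.1500
  rho_2: 0.9985
  phi_1: 0.5233
  phi_2: 0.9416
  K_S: 6.6604e+04
initial_state:
  S_U: 2.1459e+07
  S_E: 6.5132e+03
  I: 99
  T_E: 76
  T_L: 7
  V_E: 8
  V_L: 0
  R_D: 4
  R_W: 93
  N_S: 1.2250e+04
  D: 2
weights:
  B1: 1
  B2: 1
  C1: 0.28
  C2: 237
cea:
  discount_rate: 0.05
  daly_per_death: 23.41
  gdp_per_capita: 2229.9
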