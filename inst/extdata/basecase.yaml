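# Packaged base-case configuration for the zoster vaccination CEA model.
#
# Published point values: vaccine prices (453.55 / 194.28 USD per dose),
# administration cost (4.24 USD per dose), acute-zoster and PHN utilities
# (0.85 / 0.74), 5% annual discount, 40-year horizon, WTP 12,681 USD/QALY,
# 30% coverage, and the initial (t = 0) vaccine efficacy anchors.
#
# PLACEHOLDERS (replace with your own source data for a substantive
# analysis): age-band HZ incidence, conditional PHN/complication
# probabilities, case fatality, recurrence, the life table, background
# utilities, disease costs, the 10/11-year efficacy endpoints, and every
# psa_spec / owsa_spec range. Magnitudes are literature-plausible only.
currency: USD
epidemiology:
  hz_incidence:
    50-59: 0.006
    60-69: 0.008
    70-79: 0.0095
    80+: 0.01
  p_phn_given_hz:
    50-59: 0.14
    60-69: 0.22
    70-79: 0.28
    80+: 0.36
  p_other_comp_given_hz:
    50-59: 0.03
    60-69: 0.03
    70-79: 0.04
    80+: 0.05
  hz_case_fatality:
    50-59: 0.0002
    60-69: 0.0005
    70-79: 0.001
    80+: 0.003
  p_recurrence: 0.006
  all_cause_mortality:
    '50': 0.003
    '51': 0.003272
    '52': 0.003568
    '53': 0.003891
    '54': 0.004243
    '55': 0.004627
    '56': 0.005045
    '57': 0.005502
    '58': 0.006
    '59': 0.006543
    '60': 0.007135
    '61': 0.007781
    '62': 0.008485
    '63': 0.009253
    '64': 0.010091
    '65': 0.011004
    '66': 0.012
    '67': 0.013086
    '68': 0.01427
    '69': 0.015562
    '70': 0.016971
    '71': 0.018507
    '72': 0.020182
    '73': 0.022008
    '74': 0.024
    '75': 0.026172
    '76': 0.028541
    '77': 0.031124
    '78': 0.033941
    '79': 0.037013
    '80': 0.040363
    '81': 0.044016
    '82': 0.048
    '83': 0.052344
    '84': 0.057082
    '85': 0.062248
    '86': 0.067882
    '87': 0.074026
    '88': 0.080726
    '89': 0.088032
    '90': 0.096
    '91': 0.104689
    '92': 0.114164
    '93': 0.124497
    '94': 0.135765
    '95': 0.148052
    '96': 0.161452
    '97': 0.176065
    '98': 0.192
    '99': 0.209377
    '100': 0.228328
costs:
  cost_hz_episode: 420.0
  cost_phn: 1700.0
  cost_other_comp: 800.0
  cost_nonmedical: 60.0
  cost_indirect: 180.0
  price_rzv_dose: 453.55
  price_zvl_dose: 194.28
  cost_admin_dose: 4.24
  cny_per_usd: 7.0467
utilities:
  u_healthy:
    '50': 0.9
    '51': 0.8975
    '52': 0.895
    '53': 0.8925
    '54': 0.89
    '55': 0.8875
    '56': 0.885
    '57': 0.8825
    '58': 0.88
    '59': 0.8775
    '60': 0.875
    '61': 0.8725
    '62': 0.87
    '63': 0.8675
    '64': 0.865
    '65': 0.8625
    '66': 0.86
    '67': 0.8575
    '68': 0.855
    '69': 0.8525
    '70': 0.85
    '71': 0.8475
    '72': 0.845
    '73': 0.8425
    '74': 0.84
    '75': 0.8375
    '76': 0.835
    '77': 0.8325
    '78': 0.83
    '79': 0.8275
    '80': 0.825
    '81': 0.8225
    '82': 0.82
    '83': 0.8175
    '84': 0.815
    '85': 0.8125
    '86': 0.81
    '87': 0.8075
    '88': 0.805
    '89': 0.8025
    '90': 0.8
    '91': 0.7975
    '92': 0.795
    '93': 0.7925
    '94': 0.79
    '95': 0.7875
    '96': 0.785
    '97': 0.7825
    '98': 0.78
    '99': 0.7775
    '100': 0.775
  u_hz: 0.85
  u_phn: 0.74
  u_other_comp: 0.8
  u_dead: 0.0
economics:
  discount_rate: 0.05
  horizon: 40
  wtp: 12681.0
  coverage: 0.3
  compliance_two_dose: 1.0
efficacy:
  anchors:
    RZV:
      50-59:
        years:
        - 0.0
        - 10.0
        ve:
        - 0.966
        - 0.75
      60-69:
        years:
        - 0.0
        - 10.0
        ve:
        - 0.974
        - 0.75
      70-79:
        years:
        - 0.0
        - 10.0
        ve:
        - 0.913
        - 0.65
      80+:
        years:
        - 0.0
        - 10.0
        ve:
        - 0.891
        - 0.6
    ZVL:
      50-59:
        years:
        - 0.0
        - 11.0
        ve:
        - 0.627
        - 0.0
      60-69:
        years:
        - 0.0
        - 11.0
        ve:
        - 0.644
        - 0.0
      70-79:
        years:
        - 0.0
        - 11.0
        ve:
        - 0.186
        - 0.0
      80+:
        years:
        - 0.0
        - 11.0
        ve:
        - 0.186
        - 0.0
  rzv_one_dose_factor: 0.9
  phn_multiplier:
    RZV: 1.0
    ZVL: 1.0
model:
  half_cycle_correction: no
  phn_exit_prob: 1.0
  comp_exit_prob: 1.0
  vaccine_disutility: 0.0
  vaccine_ae_cost: 0.0
psa_spec:
- path: epidemiology.hz_incidence.50-59
  family: beta
  low: 0.0045
  high: 0.0075
- path: epidemiology.p_phn_given_hz.50-59
  family: beta
  low: 0.105
  high: 0.175
- path: efficacy.anchors.RZV.50-59.ve.1
  family: beta
  low: 0.8694
  high: 0.99
- path: efficacy.anchors.ZVL.50-59.ve.1
  family: beta
  low: 0.5016
  high: 0.7524
- path: epidemiology.hz_incidence.60-69
  family: beta
  low: 0.006
  high: 0.01
- path: epidemiology.p_phn_given_hz.60-69
  family: beta
  low: 0.165
  high: 0.275
- path: efficacy.anchors.RZV.60-69.ve.1
  family: beta
  low: 0.8766
  high: 0.99
- path: efficacy.anchors.ZVL.60-69.ve.1
  family: beta
  low: 0.5152
  high: 0.7728
- path: epidemiology.hz_incidence.70-79
  family: beta
  low: 0.007125
  high: 0.011875
- path: epidemiology.p_phn_given_hz.70-79
  family: beta
  low: 0.21
  high: 0.35
- path: efficacy.anchors.RZV.70-79.ve.1
  family: beta
  low: 0.8217
  high: 0.94039
- path: efficacy.anchors.ZVL.70-79.ve.1
  family: beta
  low: 0.1488
  high: 0.2232
- path: epidemiology.hz_incidence.80+
  family: beta
  low: 0.0075
  high: 0.0125
- path: epidemiology.p_phn_given_hz.80+
  family: beta
  low: 0.27
  high: 0.45
- path: efficacy.anchors.RZV.80+.ve.1
  family: beta
  low: 0.8019
  high: 0.91773
- path: efficacy.anchors.ZVL.80+.ve.1
  family: beta
  low: 0.1488
  high: 0.2232
- path: costs.cost_hz_episode
  family: gamma
  low: 336.0
  high: 504.0
- path: costs.cost_phn
  family: gamma
  low: 1360.0
  high: 2040.0
- path: costs.cost_other_comp
  family: gamma
  low: 640.0
  high: 960.0
- path: costs.cost_nonmedical
  family: gamma
  low: 48.0
  high: 72.0
- path: costs.cost_indirect
  family: gamma
  low: 144.0
  high: 216.0
- path: utilities.u_hz
  family: beta
  low: 0.8
  high: 0.9
- path: utilities.u_phn
  family: beta
  low: 0.66
  high: 0.82
- path: epidemiology.p_recurrence
  family: beta
  low: 0.003
  high: 0.012
owsa_spec:
- path: epidemiology.hz_incidence.50-59
  low: 0.0045
  high: 0.0075
- path: epidemiology.p_phn_given_hz.50-59
  low: 0.105
  high: 0.175
- path: efficacy.anchors.RZV.50-59.ve.1
  low: 0.8694
  high: 0.99
- path: efficacy.anchors.ZVL.50-59.ve.1
  low: 0.5016
  high: 0.7524
- path: epidemiology.hz_incidence.60-69
  low: 0.006
  high: 0.01
- path: epidemiology.p_phn_given_hz.60-69
  low: 0.165
  high: 0.275
- path: efficacy.anchors.RZV.60-69.ve.1
  low: 0.8766
  high: 0.99
- path: efficacy.anchors.ZVL.60-69.ve.1
  low: 0.5152
  high: 0.7728
- path: epidemiology.hz_incidence.70-79
  low: 0.007125
  high: 0.011875
- path: epidemiology.p_phn_given_hz.70-79
  low: 0.21
  high: 0.35
- path: efficacy.anchors.RZV.70-79.ve.1
  low: 0.8217
  high: 0.94039
- path: efficacy.anchors.ZVL.70-79.ve.1
  low: 0.1488
  high: 0.2232
- path: epidemiology.hz_incidence.80+
  low: 0.0075
  high: 0.0125
- path: epidemiology.p_phn_given_hz.80+
  low: 0.27
  high: 0.45
- path: efficacy.anchors.RZV.80+.ve.1
  low: 0.8019
  high: 0.91773
- path: efficacy.anchors.ZVL.80+.ve.1
  low: 0.1488
  high: 0.2232
- path: costs.cost_hz_episode
  low: 336.0
  high: 504.0
- path: costs.cost_phn
  low: 1360.0
  high: 2040.0
- path: costs.cost_other_comp
  low: 640.0
  high: 960.0
- path: costs.cost_nonmedical
  low: 48.0
  high: 72.0
- path: costs.cost_indirect
  low: 144.0
  high: 216.0
- path: utilities.u_hz
  low: 0.8
  high: 0.9
- path: utilities.u_phn
  low: 0.66
  high: 0.82
- path: epidemiology.p_recurrence
  low: 0.003
  high: 0.012
- path: economics.discount_rate
  low: 0.0
  high: 0.08

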