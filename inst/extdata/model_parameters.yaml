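subgroups:
  id:
  - NH-White
  - NH-Black
  - Asian
  - Hispanic
  general_share:
  - 0.6057
  - 0.1389
  - 0.0623
  - 0.1931
  baseline_qale:
  - 68.798000000000002
  - 65.445999999999998
  - 74.878
  - 71.762
  incidence_rate:
  - 23.0
  - 25.699999999999999
  - 18.0
  - 11.6
  life_expectancy:
  - 78.799999999999997
  - 74.799999999999997
  - 85.599999999999994
  - 80.200000000000003
  insufficient_tissue:
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  calibration_hr:
  - 1.345
  - 1.461
  - 1.419
  - 1.432
  egfr_adjustment_hr:
  - 0.675
  - 0.675
  - 0.75
  - 0.675
  lifetime_risk_override:
  - .na.real
  - .na.real
  - .na.real
  - .na.real
mutations:
  names:
  - EGFR
  - ALK
  - KRAS
  - ROS1
  - BRAF
  - NTRK
  - MET
  - RET
  prevalence:
    NH-White:
      EGFR: 0.129
      ALK: 0.022
      KRAS: 0.138
      ROS1: 0.01
      BRAF: 0.018
      NTRK: 0.001
      MET: 0.029
      RET: 0.01
      none: 0.643
    NH-Black:
      EGFR: 0.204
      ALK: 0.032
      KRAS: 0.097
      ROS1: 0.022
      BRAF: 0.032
      NTRK: 0.011
      MET: 0.0
      RET: 0.022
      none: 0.58
    Asian:
      EGFR: 0.524
      ALK: 0.048
      KRAS: 0.032
      ROS1: 0.016
      BRAF: 0.008
      NTRK: 0.0
      MET: 0.016
      RET: 0.016
      none: 0.339
    Hispanic:
      EGFR: 0.145
      ALK: 0.018
      KRAS: 0.055
      ROS1: 0.0
      BRAF: 0.036
      NTRK: 0.0
      MET: 0.036
      RET: 0.055
      none: 0.654
  'n':
    NH-White: 2778.0
    NH-Black: 93.0
    Asian: 124.0
    Hispanic: 55.0
pdl1:
  levels:
  - TPS>=50
  - TPS1-49
  - TPS<1
  distribution:
    NH-White:
      TPS>=50: 0.338
      TPS1-49: 0.338
      TPS<1: 0.325
    NH-Black:
      TPS>=50: 0.254
      TPS1-49: 0.153
      TPS<1: 0.593
    Asian:
      TPS>=50: 0.336
      TPS1-49: 0.328
      TPS<1: 0.335
    Hispanic:
      TPS>=50: 0.708
      TPS1-49: 0.208
      TPS<1: 0.083
  'n':
    NH-White: 305.0
    NH-Black: 59.0
    Asian: 128.0
    Hispanic: 120.0
lb_test:
  marker:
  - EGFR
  - ALK
  - KRAS
  - ROS1
  - BRAF
  - NTRK
  - MET
  - RET
  'n':
  - 168.0
  - 301.0
  - 147.0
  - 301.0
  - 151.0
  - 301.0
  - 143.0
  - 301.0
  tp:
  - 0.083
  - 0.01
  - 0.327
  - 0.01
  - 0.04
  - 0.01
  - 0.028
  - 0.01
  fp:
  - 0.006
  - 0.003
  - 0.007
  - 0.003
  - 0.007
  - 0.003
  - 0.007
  - 0.003
  tn:
  - 0.875
  - 0.973
  - 0.585
  - 0.973
  - 0.934
  - 0.973
  - 0.937
  - 0.973
  fn:
  - 0.036
  - 0.013
  - 0.082
  - 0.013
  - 0.02
  - 0.013
  - 0.028
  - 0.013
tb_test:
  'n': 200.0
  tp: 0.495
  fp: 0.005
  tn: 0.495
  fn: 0.005
survival:
  context:
  - EGFR
  - ALK
  - KRAS
  - ROS1
  - BRAF
  - NTRK
  - MET
  - RET
  - PD-L1>=50
  - PD-L1 1-49
  - wild type
  - EGFR
  - ALK
  - KRAS
  - ROS1
  - BRAF
  - NTRK
  - MET
  - RET
  - PD-L1>=50
  - PD-L1 1-49
  - wild type
  outcome:
  - PFS
  - PFS
  - PFS
  - PFS
  - PFS
  - PFS
  - PFS
  - PFS
  - PFS
  - PFS
  - PFS
  - OS
  - OS
  - OS
  - OS
  - OS
  - OS
  - OS
  - OS
  - OS
  - OS
  - OS
  log_scale:
  - -0.5511
  - -0.0388
  - -0.1532
  - -0.6338
  - -0.1386
  - -1.181
  - -0.7555
  - -0.3707
  - -0.5142
  - 0.2313
  - 0.2879
  - -1.1604
  - -1.0618
  - -0.7059
  - -1.6419
  - -1.2094
  - -2.289
  - -1.2892
  - -1.7389
  - -1.1603
  - -0.6783
  - -0.693
  log_scale_se:
  - 0.0514
  - 0.048
  - 0.0478
  - 0.1415
  - 0.1859
  - 0.4178
  - 0.1891
  - 0.1547
  - 0.0954
  - 0.1264
  - 0.1254
  - 0.0659
  - 0.0675
  - 0.1091
  - 0.2177
  - 0.2811
  - 0.6915
  - 0.205
  - 0.2681
  - 0.1114
  - 0.1573
  - 0.1594
  shape:
  - 0.1378
  - -0.0542
  - -0.317
  - -0.1189
  - 0.0855
  - -0.1083
  - -0.0202
  - 0.2126
  - 0.1492
  - -0.0046
  - 0.1068
  - 0.1046
  - -0.1311
  - -0.317
  - -0.1847
  - 0.1381
  - 0.4589
  - 0.2974
  - -0.1642
  - 0.0659
  - 0.091
  - 0.1994
  shape_se:
  - 0.0313
  - 0.0377
  - 0.0955
  - 0.1177
  - 0.1387
  - 0.3434
  - 0.1514
  - 0.1247
  - 0.0628
  - 0.1027
  - 0.0968
  - 0.0364
  - 0.0507
  - 0.0955
  - 0.182
  - 0.1794
  - 0.3686
  - 0.1469
  - 0.2318
  - 0.0761
  - 0.1312
  - 0.129
  correlation:
  - -0.5863
  - -0.1127
  - 0.0
  - -0.2741
  - -0.3093
  - -0.2122
  - 0.0313
  - 0.1699
  - -0.4095
  - 0.0789
  - 0.0752
  - -0.7443
  - -0.4514
  - -0.0138
  - -0.3954
  - -0.6516
  - -0.6907
  - -0.3873
  - 0.0811
  - -0.5963
  - -0.3198
  - -0.292
mismatch_hr:
  label:
  - FP EGFR
  - FP ALK
  - FP KRAS
  - FP ROS1
  - FP BRAF
  - FP NTRK
  - FP MET
  - FP RET
  - TP PD-L1 + FN mut.
  - FP PD-L1 + FN mut.
  - FN PD-L1 + FN mut.
  - TN PD-L1 + FN mut.
  - FP PD-L1 + TN mut.
  - FN PD-L1 + TN mut.
  hr:
  - 1.85
  - 3.45
  - 1.03
  - 1.06
  - 1.16
  - 1.3
  - 1.18
  - 1.59
  - 1.34
  - 1.58
  - 1.14
  - 1.34
  - 1.18
  - 0.85
  ci_low:
  - 1.26
  - 2.13
  - 0.93
  - 0.93
  - 1.03
  - 1.1
  - 0.99
  - 1.1
  - 0.89
  - 1.05
  - 0.76
  - 0.89
  - 0.97
  - 0.7
  ci_high:
  - 2.72
  - 5.57
  - 1.14
  - 1.22
  - 1.31
  - 1.54
  - 1.39
  - 2.28
  - 2.01
  - 2.37
  - 1.7
  - 2.01
  - 1.44
  - 1.03
tat_hr:
  scenario:
  - 3-week
  - 1-week
  hr:
  - 0.72
  - 0.9
  ci_low:
  - 0.56
  - 0.82
  ci_high:
  - 0.93
  - 0.98
utilities:
  state:
  - pre-progression
  - post-progression
  mean:
  - 0.71
  - 0.67
  ci_low:
  - 0.67
  - 0.59
  ci_high:
  - 0.76
  - 0.75
costs:
  payer_mix:
    medicare: 0.674
    commercial: 0.326
  lb_ngs:
    medicare: 3425.0
    commercial: 6722.0
  rebiopsy:
    medicare: 324.0
    commercial: 1628.0
  rebiopsy_complication:
    medicare: 4020.0
    commercial: 18290.0
  tb_ngs:
    medicare: 1773.0
    commercial: 4758.0
  complication_prob:
  - 0.073
  complication_se:
  - 0.00365
  mgmt_pre:
    medicare: 12254.0
    commercial: 42875.0
  mgmt_pre_se:
    medicare: 613.0
    commercial: 2144.0
  mgmt_post:
    medicare: 85250.0
    commercial: 153680.0
  mgmt_post_se:
    medicare: 4263.0
    commercial: 7684.0
  drug:
    context:
    - EGFR
    - ALK
    - KRAS
    - ROS1
    - BRAF
    - NTRK
    - MET
    - RET
    - PD-L1>=50
    - PD-L1 1-49
    - wild type
    year1:
    - 178132.0
    - 205476.0
    - 185608.0
    - 221185.0
    - 313415.0
    - 406928.0
    - 185711.0
    - 237320.0
    - 180187.0
    - 197393.0
    - 195869.0
    year2:
    - 178132.0
    - 205476.0
    - 185465.0
    - 221185.0
    - 313415.0
    - 406928.0
    - 185711.0
    - 237320.0
    - 180187.0
    - 183115.0
    - 183383.0
    year2plus:
    - 178132.0
    - 205476.0
    - 7803.0
    - 221185.0
    - 313415.0
    - 406928.0
    - 185711.0
    - 237320.0
    - 0.0
    - 5453.0
    - 5721.0
    second_line:
    - 83423.0
    - 54132.0
    - 58484.0
    - 56714.0
    - 57477.0
    - 57477.0
    - 57477.0
    - 57477.0
    - 1400.0
    - 738.0
    - 738.0
    sl_duration_ratio:
    - 0.583
    - 0.62
    - 0.365
    - 0.583
    - 0.62
    - 0.62
    - 0.62
    - 0.62
    - 0.692
    - 0.365
    - 0.365
  bsc_fraction:
  - 0.5
settings:
  discount_rate: 0.03
  threshold: 150000.0
  atkinson_aversion: 11.0
  kolm_aversion: 0.15
  tat_scenario: 3-week
  include_treatment_costs: no
  horizon_years: 20.0
  time_step_years: 0.019230769230769
  n_draws: 5000.0
  weibull_form: rate-power
  hr_application: ph
  calibration_scope: both
  io_cap_years: .inf
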