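settings:
  cycle_length_days: 21.0
  horizon_years: 10.0
  discount_annual: 0.05
  wtp: 268074.0
conventions:
  platinum: cisplatin
  mix_cisplatin: 0.5
  n_sub_cycles: 6.0
  ae_duration_cycles: 1.0
  half_cycle: none
  cost_timing: start
  induction_costing: alive
  followup_states: alive
  psa_survival: yes
arms:
- name: placebo
  induction_cycles: 4
  subsequent_param: sub_prop_placebo
- name: tislelizumab
  induction_cycles: 4
  subsequent_param: sub_prop_tislelizumab
  maintenance_cost_param: cost_tislelizumab
parameters:
  surv_tislelizumab_os_scale:
    base: 16.50756
    low: 16.50756
    high: 16.50756
    psa: fixed
  surv_tislelizumab_os_shape:
    base: 1.70402
    low: 1.70402
    high: 1.70402
    psa: fixed
  surv_tislelizumab_pfs_scale:
    base: 5.6371
    low: 5.6371
    high: 5.6371
    psa: fixed
  surv_tislelizumab_pfs_shape:
    base: 1.81906
    low: 1.81906
    high: 1.81906
    psa: fixed
  surv_placebo_os_scale:
    base: 14.9796
    low: 14.9796
    high: 14.9796
    psa: fixed
  surv_placebo_os_shape:
    base: 1.9698
    low: 1.9698
    high: 1.9698
    psa: fixed
  surv_placebo_pfs_scale:
    base: 4.94181
    low: 4.94181
    high: 4.94181
    psa: fixed
  surv_placebo_pfs_shape:
    base: 2.51144
    low: 2.51144
    high: 2.51144
    psa: fixed
  cost_tislelizumab:
    base: 2507.06
    low: 2507.06
    high: 2755.0
    psa: gamma
  cost_cisplatin:
    base: 102.81
    low: 82.22
    high: 641.13
    psa: gamma
  cost_carboplatin:
    base: 521.03
    low: 132.3
    high: 1420.0
    psa: gamma
  cost_etoposide:
    base: 1630.56
    low: 40.2
    high: 3250.16
    psa: gamma
  cost_bsc:
    base: 2467.0
    low: 1973.65
    high: 2960.47
    psa: gamma
  cost_followup:
    base: 600.58
    low: 480.46
    high: 720.7
    psa: gamma
  cost_ae_neutropenia:
    base: 607.45
    low: 485.92
    high: 728.91
    psa: gamma
  cost_ae_wbc_decreased:
    base: 3361.5
    low: 2689.19
    high: 4033.79
    psa: gamma
  cost_ae_thrombocytopenia:
    base: 7603.0
    low: 6082.42
    high: 9123.639999999999
    psa: gamma
  cost_ae_anemia:
    base: 3665.9
    low: 2932.73
    high: 4399.07
    psa: gamma
  risk_tislelizumab_neutropenia:
    base: 0.5595
    low: 0.504
    high: 0.615
    psa: beta
  risk_tislelizumab_wbc_decreased:
    base: 0.2379
    low: 0.214
    high: 0.262
    psa: beta
  risk_tislelizumab_thrombocytopenia:
    base: 0.1938
    low: 0.174
    high: 0.213
    psa: beta
  risk_tislelizumab_anemia:
    base: 0.163
    low: 0.147
    high: 0.179
    psa: beta
  risk_placebo_neutropenia:
    base: 0.5459
    low: 0.491
    high: 0.6
    psa: beta
  risk_placebo_wbc_decreased:
    base: 0.2751
    low: 0.248
    high: 0.303
    psa: beta
  risk_placebo_thrombocytopenia:
    base: 0.2533
    low: 0.228
    high: 0.279
    psa: beta
  risk_placebo_anemia:
    base: 0.1659
    low: 0.149
    high: 0.182
    psa: beta
  sub_prop_tislelizumab:
    base: 0.55
    low: 0.495
    high: 0.605
    psa: beta
  sub_prop_placebo:
    base: 0.67
    low: 0.603
    high: 0.737
    psa: beta
  utility_pfs:
    base: 0.804
    low: 0.724
    high: 0.884
    psa: beta
  utility_pd:
    base: 0.321
    low: 0.289
    high: 0.353
    psa: beta
  disutility_neutropenia:
    base: 0.2
    low: 0.18
    high: 0.22
    psa: beta
  disutility_wbc_decreased:
    base: 0.2
    low: 0.18
    high: 0.22
    psa: beta
  disutility_thrombocytopenia:
    base: 0.19
    low: 0.171
    high: 0.209
    psa: beta
  disutility_anemia:
    base: 0.078
    low: 0.07
    high: 0.086
    psa: beta
  discount_rate:
    base: 0.05
    low: 0.0
    high: 0.08
    psa: fixed
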