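version: 1
rules:
  general_medicine_cvd:
    share: 0.179
    source: pan-European survey of General Medicine case-mix (CVD-related admissions)
  stroke_tia_vs_neurology:
    share: 0.30
    source: NHS England ratio of stroke/TIA services to neurology services
  vascular_vs_general_surgery:
    share: 0.072
    source: NHS England ratio of vascular surgery to general surgery consultations
  primary_care_hypertension_proxy:
    share: 0.12
    source: proportion of GP consultations attributable to hypertension (2017), CVD proxy
  vad_share_of_dementia:
    share: 0.17
    source: proportion of all dementia attributed to vascular dementia
  cvd_share_of_high_cost_devices:
    share: 0.445
    source: CVD share of NHS England high-cost device and goods expenditure
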