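# Base-case configuration, UK 2018 prices.
#
# Costs, utilities, event disutilities, mortality relative risks, drug and
# replacement-class prices are published UK-2018 point estimates. The annual
# transition/exacerbation probabilities, per-arm 52-week trial outputs, the
# pneumonia cost decomposition, the replacement-class mixes and the life
# table are SYNTHETIC stand-ins: chosen to be clinically plausible and
# internally consistent with the published aggregates, not transcriptions of
# the (unpublished) source tables.
meta:
  provenance: >-
    published UK-2018 point estimates for costs, utilities, disutilities,
    mortality relative risks and drug prices; synthetic stand-ins for trial
    outputs, transition probabilities, class mixes and the life table
  currency: GBP-2018
  transcription_complete: false

settings:
  horizon_years: 35
  discount_cost: 0.035
  discount_benefit: 0.035
  start_age: 65.3
  male_fraction: 0.66
  perspective: health_service

transitions:
  severity: [moderate, severe, very_severe]
  p_to_severe: [0.07, 0.0, 0.0]
  p_to_very_severe: [0.0, 0.10, 0.0]

exacerbation:
  severity: [moderate, moderate, severe, severe, very_severe, very_severe]
  stratum: [no_recent, recent, no_recent, recent, no_recent, recent]
  p_moderate: [0.40, 0.54, 0.50, 0.675, 0.625, 0.84375]
  p_severe: [0.10, 0.135, 0.125, 0.16875, 0.15625, 0.2109375]

mortality:
  relative_risk:
    moderate: 1.89
    severe: 3.63
    very_severe: 8.33
  life_table: life_table_synthetic_uk.csv

costs:
  maintenance:
    moderate: 216.82
    severe: 798.95
    very_severe: 2297.98
  moderate_exacerbation: 568.48
  severe_exacerbation: 6120.30
  # weighted per-event pneumonia cost is derived at load time:
  # 0.45 * ambulatory + 0.55 * inpatient = 1087.98
  pneumonia_ambulatory: 400.0
  pneumonia_inpatient: 1650.872727272727
  p_pneumonia_hospitalised: 0.55
  replacement_class:
    lama: 29.29
    ics_laba: 31.79
    lama_laba: 32.50
    ics_lama_laba: 61.08
  societal:
    per_moderate_exac: 120.0
    per_severe_exac: 850.0
    per_pneumonia: 300.0
    per_severity_year:
      moderate: 150.0
      severe: 400.0
      very_severe: 900.0

utilities:
  state:
    moderate: 0.787
    severe: 0.750
    very_severe: 0.647
  state_ci:
    severity: [moderate, severe, very_severe]
    lower: [0.771, 0.731, 0.598]
    upper: [0.802, 0.786, 0.695]
  disutility:
    moderate_exac: 0.011
    severe_exac: 0.020
    pneumonia: 0.011
  disutility_ci:
    event: [moderate_exac, severe_exac, pneumonia]
    lower: [0.006, 0.020, 0.006]
    upper: [0.020, 0.030, 0.020]
  trial_baseline: 0.72
  trial_trajectory:
    arm: [FF_UMEC_VI, FF_UMEC_VI, FF_UMEC_VI, FF_VI, FF_VI, FF_VI, UMEC_VI, UMEC_VI, UMEC_VI]
    week: [4, 28, 52, 4, 28, 52, 4, 28, 52]
    delta: [0.020, 0.028, 0.025, 0.008, 0.012, 0.010, 0.012, 0.018, 0.015]

arms:
  FF_UMEC_VI:
    drug_cost_30d: 44.50
    rate_moderate: 0.78
    rate_severe: 0.13
    p_pneumonia: 0.08
    p_death: 0.012
    p_discontinuation: 0.18
    # class mix solves to the published 30-day replacement cost 48.01
    replacement_mix:
      lama: 0.110009426974615
      ics_laba: 0.198016968554306
      lama_laba: 0.132011312369537
      ics_lama_laba: 0.559962292101542
    trial_end:
      moderate.no_recent: 0.16080
      moderate.recent: 0.23920
      severe.no_recent: 0.16482
      severe.recent: 0.24518
      very_severe.no_recent: 0.07638
      very_severe.recent: 0.11362
  FF_VI:
    drug_cost_30d: 22.00
    rate_moderate: 0.92
    rate_severe: 0.15
    p_pneumonia: 0.07
    p_death: 0.012
    p_discontinuation: 0.22
    # class mix solves to the published 30-day replacement cost 49.34
    replacement_mix:
      lama: 0.0988148946198909
      ics_laba: 0.1778668103158036
      lama_laba: 0.1185778735438690
      ics_lama_laba: 0.6047404215204365
    trial_end:
      moderate.no_recent: 0.12348
      moderate.recent: 0.23652
      severe.no_recent: 0.14749
      severe.recent: 0.28251
      very_severe.no_recent: 0.07203
      very_severe.recent: 0.13797
  UMEC_VI:
    drug_cost_30d: 32.50
    rate_moderate: 1.02
    rate_severe: 0.19
    p_pneumonia: 0.05
    p_death: 0.019
    p_discontinuation: 0.20
    # class mix solves to the published 30-day replacement cost 48.54
    replacement_mix:
      lama: 0.105548447915965
      ics_laba: 0.189987206248737
      lama_laba: 0.126658137499158
      ics_lama_laba: 0.577806208336139
    trial_end:
      moderate.no_recent: 0.11324
      moderate.recent: 0.26676
      severe.no_recent: 0.12516
      severe.recent: 0.29484
      very_severe.no_recent: 0.05960
      very_severe.recent: 0.14040
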