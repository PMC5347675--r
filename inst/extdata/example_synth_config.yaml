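# Synthetic two-arm report collection with known reporting-probability ratios.
seed: 42
drugs:
  - drug: FINASTERIDE
    n_reports: 2000
    p_male: 0.5
    p_sex_missing: 0.02
    p_offlabel_indication: 0.05
  - drug: MINOXIDIL
    n_reports: 2000
    p_male: 0.5
    p_sex_missing: 0.02
    p_offlabel_indication: 0.05
event_probs:
  - drug: FINASTERIDE
    event: ERECTILE DYSFUNCTION
    p_male: 0.40
    p_female: 0.0
  - drug: MINOXIDIL
    event: ERECTILE DYSFUNCTION
    p_male: 0.05
    p_female: 0.0
  - drug: FINASTERIDE
    event: ABORTION INDUCED
    p_male: 0.0
    p_female: 0.16
  - drug: MINOXIDIL
    event: ABORTION INDUCED
    p_male: 0.0
    p_female: 0.02
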