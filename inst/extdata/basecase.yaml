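# Base-case configuration: Southmead Hospital cohort (2013-14) induced with
# the dinoprostone vaginal insert (DVI) vs the misoprostol vaginal insert
# (MVI). Anchor proportions and safety rates come from the EXPEDITE-based
# efficacy/safety set; the care schedule is the hospital's reported
# practice. schema: inductmod-config v1
cohort:
  n_total: 1397
  parous: 741
  nulliparous: 656
  annual_births: 6140
anchors:
  dvi_parous: {p_vd_12h: 0.183, p_vd_24h: 0.543, cs_total: 0.271}
  dvi_nulliparous: {p_vd_12h: 0.016, p_vd_24h: 0.131, cs_total: 0.271}
  mvi_parous: {p_vd_12h: 0.356, p_vd_24h: 0.700, cs_total: 0.260}
  mvi_nulliparous: {p_vd_12h: 0.059, p_vd_24h: 0.271, cs_total: 0.260}
clinical:
  oxytocin_prob:
    dvi: 0.75            # reported: three quarters of DVI inductions
    mvi: 0.4709302       # 0.75 x 27/43, from the annual set-up shift counts
  oxytocin_duration_h: {dvi: 14, mvi: 11}
  active_labour_h: 5     # 4 h first stage + 1 h second stage
  inpatient_stay_h: 24
ae_rates:
  dvi:
    total_ae: 0.026
    tachysystole_no_fhr: 0.006
    tachysystole_fhr: 0.012
    pph: 0.001
    meconium: 0.006
    nicu_admission: 0.001
    low_apgar: 0.0
    uterine_rupture: 0.0
    neonatal_acidosis: 0.0
  mvi:
    total_ae: 0.100
    tachysystole_no_fhr: 0.019
    tachysystole_fhr: 0.060
    pph: 0.0
    meconium: 0.012
    nicu_admission: 0.006
    low_apgar: 0.001
    uterine_rupture: 0.001
    neonatal_acidosis: 0.001
schedule:
  ve_duration_min: 10
  ve_interval_active_h: 4
  ve_interval_active_oxy_h: 3
  vsm_duration_min: 3
  vsm_interval_pre_h: 4
  vsm_interval_stage1_h: 4
  vsm_interval_stage2_h: 1
  oxy_setup_min_per_midwife: 10
  oxy_setup_midwives: 2
staffing:
  shift_length_h: 8
  current_births_per_midwife: 33.0
  recommended_ratio: 29.5
sensitivity:
  parameters: [ve_duration, vsm_duration, oxytocin_setup_duration, ve_frequency]
  factors: [0.5, 1.0, 1.5]
model:
  family: weibull
  horizon: 120
  residual_threshold: 0.001
validation:
  n_per_stratum: 100000
seed: 20160210
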