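# Two-level factor hierarchy for the dementia prediction model:
# concept groups of related baseline factors, each aggregated into one
# intermediate index value before recursion to the total.
groups:
  - name: sociodemographics
    variables:
      - {name: age, kind: continuous}
      - {name: male, kind: binary}
      - {name: education, kind: continuous}
      - {name: social_class, kind: ordinal}
  - name: cognition
    variables:
      - {name: mmse_total, kind: ordinal}
      - {name: mmse_calculation, kind: ordinal}
      - {name: mmse_orientation, kind: ordinal}
      - {name: mmse_other, kind: ordinal}
      - {name: mmse_wordlist, kind: ordinal}
      - {name: spmsq, kind: ordinal}
  - name: functioning
    variables:
      - {name: adl_iadl_sum, kind: continuous}
      - {name: competence_daily_activities, kind: ordinal}
      - {name: subjective_memory_decline, kind: ordinal}
  - name: apoe
    variables:
      - {name: apoe_e2_carrier, kind: binary, screen_with: apoe_genotype}
      - {name: apoe_e4_carrier, kind: binary, screen_with: apoe_genotype}
      - {name: apoe_e3e3, kind: binary, screen_with: apoe_genotype}
      - {name: apoe_genotype, kind: categorical}
  - name: comorbidity
    variables:
      - {name: cardiovascular, kind: binary}
      - {name: cerebrovascular, kind: binary}
      - {name: diabetes, kind: binary}
  - name: cholesterol
    variables:
      - {name: total_cholesterol, kind: continuous}
      - {name: ldl_cholesterol, kind: continuous}
      - {name: hdl_cholesterol, kind: continuous}
  - name: blood_pressure
    variables:
      - {name: systolic_bp, kind: continuous}
      - {name: diastolic_bp, kind: continuous}
  - name: lifestyle
    variables:
      - {name: bmi, kind: continuous}
      - {name: no_alcohol, kind: binary}
      - {name: nonsmoker, kind: binary}
  - name: depressive_symptoms
    variables:
      - {name: zung_depression, kind: continuous}
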