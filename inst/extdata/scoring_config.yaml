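# Plan-quality scoring configuration: 21 piecewise-linear dosimetric
# criteria whose maximum points sum to 150. Metric values are computed from
# raw voxel doses (cGy); breakpoints interpolate linearly and clamp at the
# ends. Target-coverage metrics score higher for higher values, organ-at-
# risk metrics for lower values. The breakpoints are implementer-chosen
# linear ramps around standard head-and-neck planning goals (at least 95%
# coverage for the 63/60 Gy PTVs, at least 90% for the 57/54 Gy PTVs,
# global hotspot below 69 Gy, parotid mean below 26 Gy, and serial-organ
# point-dose limits).
# tpp_map pairs each adjustable priority placeholder with the metrics of
# its structure, used to build the agent's structure-coded vector.
metrics:
  - {name: V_PTV63, structure: PTV63, kind: volume_at_dose_pct, threshold: 6300,
     max_points: 15, breakpoints: [{value: 85, points: 0}, {value: 95, points: 15}]}
  - {name: V_PTV60, structure: PTV60, kind: volume_at_dose_pct, threshold: 6000,
     max_points: 15, breakpoints: [{value: 85, points: 0}, {value: 95, points: 15}]}
  - {name: V_PTV57, structure: PTV57, kind: volume_at_dose_pct, threshold: 5700,
     max_points: 13, breakpoints: [{value: 80, points: 0}, {value: 90, points: 13}]}
  - {name: V_PTV54, structure: PTV54, kind: volume_at_dose_pct, threshold: 5400,
     max_points: 13, breakpoints: [{value: 80, points: 0}, {value: 90, points: 13}]}
  - {name: D_Body_0.03cc, structure: BODY, kind: dose_at_volume_cc, threshold: 0.03,
     max_points: 8, breakpoints: [{value: 6900, points: 8}, {value: 7500, points: 0}]}
  - {name: D_PTV63_0.03cc, structure: PTV63, kind: dose_at_volume_cc, threshold: 0.03,
     max_points: 8, breakpoints: [{value: 6900, points: 8}, {value: 7500, points: 0}]}
  - {name: D_Cord_0.03cc, structure: Cord, kind: dose_at_volume_cc, threshold: 0.03,
     max_points: 5, breakpoints: [{value: 3000, points: 5}, {value: 4500, points: 0}]}
  - {name: D_CordPlus5_0.03cc, structure: Cord+5mm, kind: dose_at_volume_cc, threshold: 0.03,
     max_points: 4, breakpoints: [{value: 3500, points: 4}, {value: 5000, points: 0}]}
  - {name: D_Brainstem_0.03cc, structure: Brainstem, kind: dose_at_volume_cc, threshold: 0.03,
     max_points: 6, breakpoints: [{value: 3000, points: 6}, {value: 5400, points: 0}]}
  - {name: D_BrachialPlexus_0.03cc, structure: Brachial Plexus, kind: dose_at_volume_cc, threshold: 0.03,
     max_points: 5, breakpoints: [{value: 6000, points: 5}, {value: 6600, points: 0}]}
  - {name: V_ParotidL_30Gy, structure: L Parotid, kind: volume_at_dose_pct, threshold: 3000,
     max_points: 6, breakpoints: [{value: 35, points: 6}, {value: 70, points: 0}]}
  - {name: D_ParotidL_mean, structure: L Parotid, kind: mean_dose, threshold: null,
     max_points: 6, breakpoints: [{value: 2600, points: 6}, {value: 4000, points: 0}]}
  - {name: V_ParotidR_30Gy, structure: R Parotid, kind: volume_at_dose_pct, threshold: 3000,
     max_points: 6, breakpoints: [{value: 35, points: 6}, {value: 70, points: 0}]}
  - {name: D_ParotidR_mean, structure: R Parotid, kind: mean_dose, threshold: null,
     max_points: 6, breakpoints: [{value: 2600, points: 6}, {value: 4000, points: 0}]}
  - {name: D_Oral_mean, structure: Oral Cavity, kind: mean_dose, threshold: null,
     max_points: 5, breakpoints: [{value: 3500, points: 5}, {value: 5000, points: 0}]}
  - {name: D_Esophagus_mean, structure: Esophagus, kind: mean_dose, threshold: null,
     max_points: 5, breakpoints: [{value: 3000, points: 5}, {value: 4500, points: 0}]}
  - {name: D_Constrictors_mean, structure: Constrictor, kind: mean_dose, threshold: null,
     max_points: 5, breakpoints: [{value: 4500, points: 5}, {value: 6000, points: 0}]}
  - {name: D_Avoidance1_mean, structure: Avoidance1, kind: mean_dose, threshold: null,
     max_points: 4, breakpoints: [{value: 3750, points: 4}, {value: 5500, points: 0}]}
  - {name: D_Avoidance2_mean, structure: Avoidance2, kind: mean_dose, threshold: null,
     max_points: 4, breakpoints: [{value: 3500, points: 4}, {value: 5500, points: 0}]}
  - {name: D_Avoidance3_0.03cc, structure: Avoidance3, kind: dose_at_volume_cc, threshold: 0.03,
     max_points: 4, breakpoints: [{value: 5700, points: 4}, {value: 6500, points: 0}]}
  - {name: D_Body_mean, structure: BODY, kind: mean_dose, threshold: null,
     max_points: 7, breakpoints: [{value: 2500, points: 7}, {value: 4500, points: 0}]}
tpp_map:
  P1: [V_ParotidL_30Gy, D_ParotidL_mean]
  P2: [V_ParotidL_30Gy, D_ParotidL_mean]
  P3: [V_ParotidR_30Gy, D_ParotidR_mean]
  P4: [V_ParotidR_30Gy, D_ParotidR_mean]
  P5: [D_Oral_mean]
  P6: [D_Constrictors_mean]
  P7: [D_Constrictors_mean]
  P8: [D_BrachialPlexus_0.03cc]
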