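# Default dichotomization recipes, one entry per cohort variable.
# method: fixed_cutoff | median_split | categorical_passthrough
# high_if: ge (default) -- value >= cutoff is the "high" state
sex:
  method: categorical_passthrough
  levels: [female, male]
  labels: {female: "Female sex", male: "Male sex"}
age:
  method: fixed_cutoff
  cutoff: 60
  labels: {high: "Old age", low: "Young age"}
joint_type:
  method: categorical_passthrough
  levels: [unilateral, bilateral]
  labels:
    unilateral: "Artificial joint type: unilateral"
    bilateral: "Artificial joint type: bilateral"
sit_to_stand_s:
  method: median_split
  labels: {high: "Decreased ability to stand", low: "Preserved ability to stand"}
bmi:
  method: fixed_cutoff
  cutoff: 30
  labels: {high: "Obesity", low: "Non-obesity"}
cci:
  method: fixed_cutoff
  cutoff: 1
  labels: {high: "Comorbidities", low: "No comorbidities"}
cesd:
  method: fixed_cutoff
  cutoff: 16
  labels: {high: "Depressive symptoms", low: "Non-depressive symptoms"}
womac_pain:
  method: median_split
  labels:
    high: "High preoperative WOMAC-pain score"
    low: "Low preoperative WOMAC-pain score"
womac_stiffness:
  method: median_split
  labels:
    high: "High preoperative WOMAC-stiffness score"
    low: "Low preoperative WOMAC-stiffness score"
womac_physfunc:
  method: median_split
  labels:
    high: "High preoperative WOMAC-physical function score"
    low: "Low preoperative WOMAC-physical function score"
pcs_pre:
  method: fixed_cutoff
  cutoff: 50
  labels: {high: "High preoperative PCS", low: "Low preoperative PCS"}
pcs_1y:
  method: fixed_cutoff
  cutoff: 50
  labels:
    high: "High PCS at 1 year postoperatively"
    low: "Low PCS at 1 year postoperatively"
pcs_2y:
  method: fixed_cutoff
  cutoff: 50
  labels:
    high: "High PCS at 2 years postoperatively"
    low: "Low PCS at 2 years postoperatively"
mcs_pre:
  method: fixed_cutoff
  cutoff: 50
  labels: {high: "High preoperative MCS", low: "Low preoperative MCS"}
mcs_1y:
  method: fixed_cutoff
  cutoff: 50
  labels:
    high: "High MCS at 1 year postoperatively"
    low: "Low MCS at 1 year postoperatively"
mcs_2y:
  method: fixed_cutoff
  cutoff: 50
  labels:
    high: "High MCS at 2 years postoperatively"
    low: "Low MCS at 2 years postoperatively"
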