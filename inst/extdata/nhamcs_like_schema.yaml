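outcome: hospital_admission
features:
- name: month
  kind: categorical
  display: month
  required: yes
  levels:
  - jan
  - feb
  - mar
  - apr
  - may
  - jun
  - jul
  - aug
  - sep
  - oct
  - nov
  - dec
- name: week
  kind: categorical
  display: week day
  required: yes
  levels:
  - monday
  - tuesday
  - wednesday
  - thursday
  - friday
  - saturday
  - sunday
- name: arrival_time
  kind: categorical
  display: arrival time
  required: yes
  levels:
  - morning
  - afternoon
  - evening
  - night
- name: age
  kind: continuous
  display: age
  required: yes
  units: years
  precision: 0
  range:
  - 0.0
  - 115.0
- name: residence
  kind: categorical
  display: residence
  required: yes
  levels:
  - private home
  - nursing home
  - homeless
  - other
- name: sex
  kind: binary
  display: sex
  required: yes
  levels:
  - female
  - male
- name: race
  kind: categorical
  display: race
  required: yes
  levels:
  - white
  - black
  - asian
  - other
- name: ambulance
  kind: binary
  display: came by ambulance
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: pay_insurance
  kind: binary
  display: pay by insurance
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: pay_medicare
  kind: binary
  display: pay by medicare
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: pay_medicaid
  kind: binary
  display: pay by medicaid
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: pay_workcomp
  kind: binary
  display: pay by work compensation
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: pay_self
  kind: binary
  display: pay by self
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: no_charge
  kind: binary
  display: no charge to pay
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: temperature
  kind: continuous
  display: body temperature
  required: yes
  units: degrees
  precision: 1
  range:
  - 25.0
  - 45.0
- name: heart_rate
  kind: continuous
  display: heart rate
  required: yes
  units: beats
  precision: 0
  range:
  - 0.0
  - 300.0
- name: respiratory_rate
  kind: continuous
  display: respiratory rate
  required: yes
  units: times
  precision: 0
  range:
  - 0.0
  - 99.0
- name: systolic_bp
  kind: continuous
  display: systolic pressure
  required: yes
  units: mmhg
  precision: 0
  range:
  - 0.0
  - 300.0
- name: diastolic_bp
  kind: continuous
  display: diastolic pressure
  required: yes
  units: mmhg
  precision: 0
  range:
  - 0.0
  - 200.0
- name: pulse_oximetry
  kind: continuous
  display: pulse oximetry
  required: yes
  units: percent
  precision: 0
  range:
  - 0.0
  - 100.0
- name: pain_scale
  kind: continuous
  display: pain index
  required: yes
  units: ''
  precision: 0
  range:
  - 0.0
  - 10.0
- name: triage_level
  kind: categorical
  display: triage level
  required: yes
  levels:
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
- name: ed_last_72h
  kind: binary
  display: seen in emergency during last 72 hours
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: dementia
  kind: binary
  display: dementia
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: cancer
  kind: binary
  display: cancer
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: cerebrovascular
  kind: binary
  display: cerebrovascular disease
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: copd
  kind: binary
  display: chronic obstructive pulmonary disease
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: heart_failure
  kind: binary
  display: heart failure
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: hiv
  kind: binary
  display: hiv
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: ecg
  kind: binary
  display: electrocardiogram
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: xray
  kind: binary
  display: x ray
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: ct_scan
  kind: binary
  display: ct scan
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: mri
  kind: binary
  display: mri
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: ultrasound
  kind: binary
  display: ultrasound
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: cpr
  kind: binary
  display: cpr
  required: yes
  levels:
  - 'no'
  - 'yes'
- name: admitted_icu
  kind: binary
  display: admitted to intensive care
  required: yes
  levels:
  - 'no'
  - 'yes'
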