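# Illustrative care-plan rule set (18 rules). The rule base used on a real
# ward is staff-authored and private; these rules demonstrate the same
# IF-THEN form over the 21 patient-state variables and cover all four plan
# actions. Evaluation is severity-first (extra_situation > adjust > monitor
# > continue_current_treatment), then priority, then id; anything unmatched
# falls through to continue_current_treatment.
default: continue_current_treatment
rules:
  - id: ES01
    if:
      - {var: Con, op: eq, value: unconscious}
    then: extra_situation
    priority: 100
  - id: ES02
    if:
      - {var: MoveH, op: eq, value: falling on the ground}
    then: extra_situation
    priority: 90
  - id: ES03
    if:
      - {var: Breath, op: eq, value: with_apnoeas}
      - {var: Sat, op: eq, value: lt94}
      - {var: PL, op: eq, value: bradycardia}
      - {var: RiskC, op: eq, value: high}
    then: extra_situation
    priority: 80
  - id: ES04
    if:
      - {var: Gly, op: eq, value: lt2.5}
      - {var: Con, op: eq, value: changed}
      - {var: Temp, op: eq, value: lt36.0}
      - {var: Sleep, op: eq, value: lt4h}
    then: extra_situation
    priority: 80
  - id: ES05
    if:
      - {var: EatC, op: eq, value: swallows_only_liquids}
      - {var: Breath, op: eq, value: increased}
      - {var: Con, op: eq, value: changed}
      - {var: Fluid, op: eq, value: lt500ml}
    then: extra_situation
    priority: 70
  - id: AD01
    if:
      - {var: Pain, op: eq, value: unbearable}
    then: adjust
    priority: 100
  - id: AD02
    if:
      - {var: BP, op: eq, value: hypertension_severe}
      - {var: Med, op: eq, value: antihypertensives}
      - {var: PL, op: eq, value: tachycardia}
    then: adjust
    priority: 80
  - id: AD03
    if:
      - {var: Temp, op: eq, value: gt38.4}
      - {var: Med, op: eq, value: antibiotics}
      - {var: Breath, op: eq, value: increased}
    then: adjust
    priority: 80
  - id: AD04
    if:
      - {var: Bedsores, op: eq, value: "yes"}
      - {var: MoveC, op: eq, value: lying}
      - {var: RiskC, op: eq, value: high}
    then: adjust
    priority: 70
  - id: AD05
    if:
      - {var: Sleep, op: eq, value: apnoea}
      - {var: Breath, op: eq, value: with_apnoeas}
      - {var: Sat, op: eq, value: lt94}
    then: adjust
    priority: 70
  - id: AD06
    if:
      - {var: BMI, op: eq, value: gt1_minus}
      - {var: EatC, op: eq, value: swallows_only_liquids}
      - {var: EatH, op: eq, value: parenteral_nutrition}
    then: adjust
    priority: 60
  - id: MO01
    if:
      - {var: RiskC, op: eq, value: high}
      - {var: Bowel, op: eq, value: diarrhoea}
      - {var: Fluid, op: eq, value: lt500ml}
    then: monitor
    priority: 80
  - id: MO02
    if:
      - {var: PL, op: eq, value: tachycardia}
      - {var: BP, op: eq, value: hypotension}
      - {var: Sat, op: eq, value: lt94}
    then: monitor
    priority: 80
  - id: MO03
    if:
      - {var: Fluid, op: eq, value: lt500ml}
      - {var: Urine, op: eq, value: concentrated}
      - {var: Sleep, op: eq, value: lt4h}
    then: monitor
    priority: 70
  - id: MO04
    if:
      - {var: Sleep, op: eq, value: lt4h}
      - {var: Pain, op: eq, value: severe}
      - {var: RiskC, op: eq, value: medium}
    then: monitor
    priority: 60
  - id: MO05
    if:
      - {var: MoveH, op: eq, value: slowed down}
      - {var: RiskC, op: eq, value: medium}
      - {var: Diseases, op: eq, value: dementia}
    then: monitor
    priority: 60
  - id: CO01
    if:
      - {var: RiskC, op: eq, value: none}
      - {var: Pain, op: eq, value: none}
    then: continue_current_treatment
    priority: 10
  - id: CO02
    if:
      - {var: MoveC, op: eq, value: independent}
      - {var: EatH, op: eq, value: independent_eating}
    then: continue_current_treatment
    priority: 10
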