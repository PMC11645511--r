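items:
- pf1
- pf2
- pf3
- pf4
- pf5
- pf6
- ft1
- ft2
- ft3
- ft4
- pi1
- pi2
- pi3
- pi4
- dp1
- dp2
- dp3
- dp4
- ax1
- ax2
- ax3
- ax4
- ap1
- ap2
- ap3
- ap4
- sl1
- sl2
- sl3
- sl4
- sl5
- sl6
- cg1
- cg2
- pr1
- pr2
- pr3
- pr4
- pr5
range:
- 1
- 5
scales:
  physical_function:
    items:
    - pf1
    - pf2
    - pf3
    - pf4
    reverse: []
  fatigue:
    items:
    - ft1
    - ft2
    - ft3
    - ft4
    reverse: []
  pain_interference:
    items:
    - pi1
    - pi2
    - pi3
    - pi4
    reverse: []
  depressive_symptoms:
    items:
    - dp1
    - dp2
    - dp3
    - dp4
    reverse: []
  anxiety:
    items:
    - ax1
    - ax2
    - ax3
    - ax4
    reverse: []
  ability_participate:
    items:
    - ap1
    - ap2
    - ap3
    - ap4
    reverse: []
  sleep_disturbance:
    items:
    - sl1
    - sl2
    - sl3
    - sl5
    reverse: sl1
  cognitive_function:
    items:
    - cg1
    - cg2
    reverse: []
batteries:
  physical_function6:
    items:
    - pf1
    - pf2
    - pf3
    - pf4
    - pf5
    - pf6
    allowed: 5
    reverse: []
  fatigue:
    items:
    - ft1
    - ft2
    - ft3
    - ft4
    allowed: .na.integer
    reverse: []
  pain_interference:
    items:
    - pi1
    - pi2
    - pi3
    - pi4
    allowed: .na.integer
    reverse: []
  depressive:
    items:
    - dp1
    - dp2
    - dp3
    - dp4
    allowed: .na.integer
    reverse: []
  anxiety:
    items:
    - ax1
    - ax2
    - ax3
    - ax4
    allowed: .na.integer
    reverse: []
  ability_participate:
    items:
    - ap1
    - ap2
    - ap3
    - ap4
    allowed: .na.integer
    reverse: []
  sleep_set1:
    items:
    - sl1
    - sl2
    - sl3
    allowed: 3
    reverse: sl1
  sleep_set2:
    items:
    - sl4
    - sl5
    - sl6
    allowed: 3
    reverse: sl4
pairs:
  pain_interference:
  - pi1
  - pr1
  trouble_doing:
  - ft2
  - pr2
  sleep_problems:
  - sl2
  - pr3
  concentrate_focus:
  - cg1
  - pr4
  memory:
  - cg2
  - pr5
conditions:
- back_pain
- neck_pain
- anxiety_dx
- depression_dx
- hypertension
- asthma
- diabetes
- heart_attack
- chd
- angina
- copd
- cancer
- stroke
- arthritis
- migraine
- thyroid
- kidney_disease
- liver_disease
- osteoporosis
- ulcer
- allergies
- insomnia_dx
- syndomitis
- chekalism
fake_conditions:
- syndomitis
- chekalism
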