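kind: linkage
mother_cutoff: 40
infant_cutoff: 31
rng_seed: 1
require_plurality_concordance: yes
ssn_requires_extra_variable: yes
maternal_passes:
- label: A
  keys:
  - mother_dob
  - hospital
  dedup_repeat: no
- label: B
  keys:
  - infant_dob
  - zip
  dedup_repeat: no
- label: C
  keys:
  - infant_dob
  - hospital
  dedup_repeat: no
- label: D
  keys:
  - mother_dob
  - zip
  dedup_repeat: no
- label: E
  keys:
  - zip
  - hospital
  dedup_repeat: no
- label: F
  keys:
  - preterm
  - infant_dob
  dedup_repeat: no
infant_passes:
- label: A
  keys:
  - hospital
  - infant_dob
  dedup_repeat: no
- label: B
  keys:
  - hospital
  - infant_dob
  dedup_repeat: yes
- label: C
  keys:
  - hospital
  - infant_dob
  dedup_repeat: yes
- label: D
  keys:
  - hospital
  - infant_dob
  dedup_repeat: yes
- label: E
  keys:
  - infant_dob
  - zip
  dedup_repeat: no
- label: F
  keys:
  - infant_dob
  - zip
  dedup_repeat: yes
- label: G
  keys:
  - zip
  - sex
  dedup_repeat: no
- label: H
  keys:
  - zip
  - payer
  dedup_repeat: no
- label: I
  keys:
  - zip
  - hospital
  dedup_repeat: no
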