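ga_lt29:
  icd9_dx:
  - '76521'
  - '76522'
  - '76523'
  - '76524'
  icd10_dx:
  - P072
ga_29to36:
  icd9_dx:
  - '76525'
  - '76526'
  - '76527'
  - '76528'
  icd10_dx:
  - O601
  - O603
  - P073
ga_37to42:
  icd9_dx:
  - '76529'
ga_gt42:
  icd10_dx:
  - P0822
  - O48
cesarean:
  icd9_dx:
  - '6697'
  - '7634'
  icd10_dx:
  - O82
  - P034
  - Z3801
  - Z3831
  - Z3862
  icd9_proc:
  - '74'
  icd10_proc:
  - 10D
previous_cesarean:
  icd9_dx:
  - '6542'
  icd10_dx:
  - O342
bw_lt2500:
  icd9_dx:
  - '76501'
  - '76502'
  - '76503'
  - '76504'
  - '76505'
  - '76506'
  - '76507'
  - '76508'
  - '76511'
  - '76512'
  - '76513'
  - '76514'
  - '76515'
  - '76516'
  - '76517'
  - '76518'
  icd10_dx:
  - P070
  - P071
  - P0501
  - P0502
  - P0503
  - P0504
  - P0505
  - P0507
  - P0508
  - P0511
  - P0512
  - P0513
  - P0514
  - P0515
  - P0517
  - P0518
bw_2500to4499:
  icd9_dx:
  - '76509'
  - '76519'
  icd10_dx:
  - P0509
  - P0519
bw_ge4500:
  icd10_dx:
  - P080
sga_lga:
  icd9_dx:
  - '6565'
  - '7640'
  - '7641'
  - '7649'
  icd10_dx:
  - P05
  - O365
hypertension_preg:
  icd9_dx:
  - '642'
  icd10_dx:
  - O1
diabetes_any:
  icd9_dx:
  - '6480'
  - '6488'
  - '250'
  icd10_dx:
  - O24
plurality_singleton:
  icd9_dx:
  - V270
  icd10_dx:
  - Z380
  - Z381
  - Z382
plurality_twin:
  icd9_dx:
  - '6510'
  icd10_dx:
  - O300
  - Z383
  - Z384
  - Z385
plurality_multiple:
  icd9_dx:
  - '6511'
  - '6512'
  icd10_dx:
  - O301
  - O302
  - O388
  - O389
  - Z386
  - Z387
  - Z388
gestational_diabetes:
  icd9_dx:
  - '6488'
  icd10_dx:
  - O244
preexisting_diabetes:
  icd9_dx:
  - '6480'
  - '250'
  icd10_dx:
  - O240
  - O241
  - O243
prepregnancy_hypertension:
  icd9_dx:
  - '6420'
  - '6421'
  - '6422'
  icd10_dx:
  - O10
  - O11
gestational_hypertension:
  icd9_dx:
  - '6423'
  - '6424'
  - '6425'
  - '6427'
  icd10_dx:
  - O13
  - O14
eclampsia:
  icd9_dx:
  - '6426'
  icd10_dx:
  - O15
placental_abruption:
  icd9_dx:
  - '6412'
  icd10_dx:
  - O45
chorioamnionitis:
  icd9_dx:
  - '6584'
  - '7627'
  icd10_dx:
  - O4112
  - P027
neural_tube_defect:
  icd9_dx:
  - '740'
  - '741'
  - '7420'
  icd10_dx:
  - Q00
  - Q01
  - Q05
gastroschisis_omphalocele:
  icd9_dx:
  - '75672'
  - '75673'
  icd10_dx:
  - Q792
  - Q793
cleft_lip_palate:
  icd9_dx:
  - '749'
  icd10_dx:
  - Q35
  - Q36
  - Q37
major_heart_defect:
  icd9_dx:
  - '745'
  - '746'
  icd10_dx:
  - Q20
  - Q21
  - Q22
  - Q23
  - Q24
  - Q25
  - Q26
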