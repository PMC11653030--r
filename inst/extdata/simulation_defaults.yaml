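n_deliveries: 1000
year_range:
- 2005
- 2020
twin_rate: 0.0303
higher_multiple_rate: 0.0011
fetal_death_rate: 0.0055
ga_band_probs:
  20-27: 0.0054
  28-31: 0.0082
  32-36: 0.0763
  37-42: 0.8987
  43-44: 0.0114
infant_death_probs:
  20-27: 0.25
  28-31: 0.06
  32-36: 0.01
  37-42: 0.002
  43-44: 0.002
p_mother_unlinked: 0.05
p_infant_unlinked: 0.03
p_dob_transposed: 0.01
p_field_missing: 0.02
p_zip_error: 0.02
enc_ssn_mother: 0.8
enc_ssn_infant: 0.05
n_hospitals: 25
n_zips: 60
rng_seed: 1
kind: simulation
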