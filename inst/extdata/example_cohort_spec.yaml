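# Example synthetic-cohort specification for `blood-audit simulate` /
# read_cohort_spec(). Transfusion pmfs echo the bundled pediatric cardiac
# cohort; every patient is crossmatched 2 adult RBC units.
seed: 2019
blocks:
  - procedure: VSD
    n_patients: 64
    crossmatch_per_patient: 2
    transfusion_pmf:
      "0": 0.125
      "1": 0.1875
      "2": 0.671875
      "3": 0.015625
  - procedure: TOF
    n_patients: 29
    crossmatch_per_patient: 2
    transfusion_pmf:
      "0": 0.3448275862068966
      "1": 0.27586206896551724
      "2": 0.3793103448275862
  - procedure: PDA
    n_patients: 3
    crossmatch_per_patient: 2
    transfusion_pmf:
      "0": 1.0
    wastage_rate: 0.0
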