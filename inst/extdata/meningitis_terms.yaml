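# Preferred-term set standing in for the noninfectious-meningitis standardized
# query (MedDRA itself is licensed and cannot be shipped). Editable.
query_id: SMQ-20000134-surrogate
match_mode: case_insensitive
terms:
  - Meningitis
  - Meningitis aseptic
  - Meningitis noninfective
  - Meningeal disorder
  - Meningism
  - Arachnoiditis
  - Meningoradiculitis
  - Pachymeningitis
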