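drug_name,drug_class
ipilimumab,CTLA4
nivolumab,PD1
pembrolizumab,PD1
cemiplimab,PD1
atezolizumab,PDL1
durvalumab,PDL1
avelumab,PDL1
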