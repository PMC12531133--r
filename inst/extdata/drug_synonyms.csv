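synonym,active_moiety
opdivo,nivolumab
nivolumab bms,nivolumab
keytruda,pembrolizumab
lambrolizumab,pembrolizumab
mk-3475,pembrolizumab
yervoy,ipilimumab
mdx-010,ipilimumab
libtayo,cemiplimab
cemiplimab-rwlc,cemiplimab
tecentriq,atezolizumab
mpdl3280a,atezolizumab
imfinzi,durvalumab
medi4736,durvalumab
bavencio,avelumab
msb0010718c,avelumab
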