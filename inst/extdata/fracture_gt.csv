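sample,gt_label
s00,B
s01,N
s02,N
s03,G
s04,B
s05,B
s06,N
s07,B
s08,N
s09,B
s10,B
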