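sample,participant,modality,angle_deg
s00,1,POCUS,3.7
s00,1,XRAY,8.7
s00,2,POCUS,0.0
s00,2,XRAY,3.0
s00,3,POCUS,
s00,3,XRAY,
s01,1,POCUS,
s01,1,XRAY,
s01,2,POCUS,
s01,2,XRAY,
s01,3,POCUS,
s01,3,XRAY,
s02,1,POCUS,
s02,1,XRAY,
s02,2,POCUS,
s02,2,XRAY,
s02,3,POCUS,
s02,3,XRAY,
s03,1,POCUS,21.0
s03,1,XRAY,10.0
s03,2,POCUS,20.0
s03,2,XRAY,8.0
s03,3,POCUS,24.0
s03,3,XRAY,8.0
s04,1,POCUS,7.9
s04,1,XRAY,15.0
s04,2,POCUS,9.0
s04,2,XRAY,8.0
s04,3,POCUS,17.0
s04,3,XRAY,5.0
s05,1,POCUS,9.1
s05,1,XRAY,7.0
s05,2,POCUS,4.0
s05,2,XRAY,2.0
s05,3,POCUS,10.0
s05,3,XRAY,7.0
s06,1,POCUS,3.0
s06,1,XRAY,
s06,2,POCUS,
s06,2,XRAY,
s06,3,POCUS,
s06,3,XRAY,
s07,1,POCUS,4.2
s07,1,XRAY,9.3
s07,2,POCUS,4.0
s07,2,XRAY,4.0
s07,3,POCUS,7.0
s07,3,XRAY,9.0
s08,1,POCUS,
s08,1,XRAY,
s08,2,POCUS,
s08,2,XRAY,
s08,3,POCUS,
s08,3,XRAY,
s09,1,POCUS,5.8
s09,1,XRAY,9.7
s09,2,POCUS,8.0
s09,2,XRAY,10.0
s09,3,POCUS,10.0
s09,3,XRAY,9.0
s10,1,POCUS,4.2
s10,1,XRAY,14.3
s10,2,POCUS,6.0
s10,2,XRAY,8.0
s10,3,POCUS,8.0
s10,3,XRAY,9.0
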