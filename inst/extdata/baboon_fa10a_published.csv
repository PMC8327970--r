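sex,metric,tooth,fa10a,n
female,breadth,MNM1,0.01,20
female,breadth,MNM2,0.01,16
female,breadth,MNM3,0.01,20
female,breadth,MNP4,0.00,14
female,breadth,MXM1,0.01,31
female,breadth,MXM2,0.01,30
female,breadth,MXM3,0.03,34
female,breadth,MXP3,0.04,26
female,breadth,MXP4,0.01,31
female,length,MNM3,0.04,20
female,length,MNP4,0.06,15
female,length,MXM1,0.02,31
female,length,MXM2,0.04,32
female,length,MXM3,0.03,32
female,length,MXP3,0.04,27
female,length,MXP4,0.05,31
male,breadth,MNM1,0.01,17
male,breadth,MNM2,0.03,16
male,breadth,MNM3,0.01,14
male,breadth,MNP4,0.01,15
male,breadth,MXM1,0.01,31
male,breadth,MXM2,0.02,34
male,breadth,MXM3,0.02,34
male,breadth,MXP3,0.03,25
male,breadth,MXP4,0.02,29
male,length,MNM3,0.08,14
male,length,MNP4,0.07,15
male,length,MXM1,0.05,33
male,length,MXM2,0.07,35
male,length,MXM3,0.08,33
male,length,MXP4,0.10,29
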