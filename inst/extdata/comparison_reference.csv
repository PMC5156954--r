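season,stage,pair,parameter,p
2007,T1,faba_bean-grass_pea,a,0.3989
2007,T1,faba_bean-grass_pea,b,0.0046
2007,T1,faba_bean-grass_pea,x0,0.0637
2007,T1,faba_bean-lentil,a,0.0000
2007,T1,faba_bean-lentil,b,0.1446
2007,T1,faba_bean-lentil,x0,0.0000
2007,T1,grass_pea-lentil,a,0.0000
2007,T1,grass_pea-lentil,b,0.0112
2007,T1,grass_pea-lentil,x0,0.0000
2007,T2,faba_bean-grass_pea,a,0.2178
2007,T2,faba_bean-grass_pea,b,0.1076
2007,T2,faba_bean-grass_pea,x0,0.0000
2007,T2,faba_bean-lentil,a,0.0000
2007,T2,faba_bean-lentil,b,0.0157
2007,T2,faba_bean-lentil,x0,0.0080
2007,T2,grass_pea-lentil,a,0.0000
2007,T2,grass_pea-lentil,b,0.1360
2007,T2,grass_pea-lentil,x0,0.0000
2007,T3,faba_bean-grass_pea,a,0.3123
2007,T3,faba_bean-grass_pea,b,0.3962
2007,T3,faba_bean-grass_pea,x0,0.0000
2007,T3,faba_bean-lentil,a,0.0000
2007,T3,faba_bean-lentil,b,0.0857
2007,T3,faba_bean-lentil,x0,0.0010
2007,T3,grass_pea-lentil,a,0.0000
2007,T3,grass_pea-lentil,b,0.0055
2007,T3,grass_pea-lentil,x0,0.0000
2007,T4,faba_bean-grass_pea,a,0.5749
2007,T4,faba_bean-grass_pea,b,0.0509
2007,T4,faba_bean-grass_pea,x0,0.0000
2007,T4,faba_bean-lentil,a,0.0000
2007,T4,faba_bean-lentil,b,0.7955
2007,T4,faba_bean-lentil,x0,0.0000
2007,T4,grass_pea-lentil,a,0.0000
2007,T4,grass_pea-lentil,b,0.2977
2007,T4,grass_pea-lentil,x0,0.0023
2007,T5,faba_bean-grass_pea,a,0.3553
2007,T5,faba_bean-grass_pea,b,0.8053
2007,T5,faba_bean-grass_pea,x0,0.6952
2007,T5,faba_bean-lentil,a,0.9304
2007,T5,faba_bean-lentil,b,0.5926
2007,T5,faba_bean-lentil,x0,0.4743
2007,T5,grass_pea-lentil,a,0.2667
2007,T5,grass_pea-lentil,b,0.4338
2007,T5,grass_pea-lentil,x0,0.2621
2007,T6,faba_bean-grass_pea,a,0.3933
2007,T6,faba_bean-grass_pea,b,0.1268
2007,T6,faba_bean-grass_pea,x0,0.8134
2008,T1,faba_bean-grass_pea,a,0.0000
2008,T1,faba_bean-grass_pea,b,0.0219
2008,T1,faba_bean-grass_pea,x0,0.0000
2008,T1,faba_bean-lentil,a,0.0000
2008,T1,faba_bean-lentil,b,0.1196
2008,T1,faba_bean-lentil,x0,0.0011
2008,T1,grass_pea-lentil,a,0.0000
2008,T1,grass_pea-lentil,b,0.0002
2008,T1,grass_pea-lentil,x0,0.0000
2008,T2,faba_bean-grass_pea,a,0.0000
2008,T2,faba_bean-grass_pea,b,0.0243
2008,T2,faba_bean-grass_pea,x0,0.0000
2008,T2,faba_bean-lentil,a,0.0000
2008,T2,faba_bean-lentil,b,0.3602
2008,T2,faba_bean-lentil,x0,0.7395
2008,T2,grass_pea-lentil,a,0.0000
2008,T2,grass_pea-lentil,b,0.0005
2008,T2,grass_pea-lentil,x0,0.0000
2008,T3,faba_bean-grass_pea,a,0.0000
2008,T3,faba_bean-grass_pea,b,0.0001
2008,T3,faba_bean-grass_pea,x0,0.0000
2008,T3,faba_bean-lentil,a,0.0000
2008,T3,faba_bean-lentil,b,0.5959
2008,T3,faba_bean-lentil,x0,0.9859
2008,T3,grass_pea-lentil,a,0.0000
2008,T3,grass_pea-lentil,b,0.0203
2008,T3,grass_pea-lentil,x0,0.0000
2008,T4,faba_bean-grass_pea,a,0.0000
2008,T4,faba_bean-grass_pea,b,0.0004
2008,T4,faba_bean-grass_pea,x0,0.0000
2008,T4,faba_bean-lentil,a,0.0000
2008,T4,faba_bean-lentil,b,0.0125
2008,T4,faba_bean-lentil,x0,0.1650
2008,T4,grass_pea-lentil,a,0.0000
2008,T4,grass_pea-lentil,b,0.3227
2008,T4,grass_pea-lentil,x0,0.0000
2008,T5,faba_bean-grass_pea,a,0.0041
2008,T5,faba_bean-grass_pea,b,0.2484
2008,T5,faba_bean-grass_pea,x0,0.0044
2008,T5,faba_bean-lentil,a,0.6036
2008,T5,faba_bean-lentil,b,0.1301
2008,T5,faba_bean-lentil,x0,0.0285
2008,T5,grass_pea-lentil,a,0.0000
2008,T5,grass_pea-lentil,b,0.0067
2008,T5,grass_pea-lentil,x0,0.2217
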