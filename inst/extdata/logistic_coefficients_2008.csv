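crop,stage,a,se_a,b,se_b,x0,se_x0,rmse
faba_bean,T1,0.7539,0.0126,-12.07,0.89,800.03,5.32,0.0306
faba_bean,T2,0.7387,0.0106,-15.08,1.03,855.39,4.09,0.0254
faba_bean,T3,0.7180,0.0102,-20.14,1.56,883.76,3.71,0.0262
faba_bean,T4,0.6997,0.0108,-21.06,1.26,1001.48,4.18,0.0193
faba_bean,T5,0.4383,0.0855,-21.09,5.64,1196.03,28.90,0.0294
grass_pea,T1,0.9343,0.0176,-9.19,0.82,718.41,6.77,0.0419
grass_pea,T2,0.9126,0.0099,-12.24,0.61,774.06,3.54,0.0256
grass_pea,T3,0.8764,0.0187,-11.78,1.08,806.34,6.79,0.0440
grass_pea,T4,0.8725,0.0226,-13.67,1.31,920.03,7.96,0.0400
grass_pea,T5,0.7680,0.0591,-13.71,1.95,1092.56,17.58,0.0376
lentil,T1,0.6132,0.0084,-14.11,0.92,823.53,4.05,0.0210
lentil,T2,0.5477,0.0061,-16.36,0.92,853.67,3.10,0.0154
lentil,T3,0.4993,0.0129,-18.56,2.50,883.62,6.94,0.0319
lentil,T4,0.4948,0.0156,-15.68,1.53,987.14,9.05,0.0233
lentil,T5,0.3911,0.0163,-35.02,6.22,1116.44,6.24,0.0226
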