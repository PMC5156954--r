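crop,stage,a,se_a,b,se_b,x0,se_x0,rmse
faba_bean,T1,0.7769,0.0170,-22.51,3.05,826.41,6.07,0.0561
faba_bean,T2,0.7635,0.0119,-21.75,1.88,897.35,3.88,0.0344
faba_bean,T3,0.7420,0.0167,-18.35,2.06,965.15,6.32,0.0435
faba_bean,T4,0.7330,0.0077,-22.48,1.38,1058.24,4.61,0.0159
faba_bean,T5,0.6425,0.1132,-15.43,3.79,1267.77,36.10,0.0353
faba_bean,T6,0.4020,0.0914,-22.03,6.86,1300.33,35.29,0.0294
grass_pea,T1,0.7941,0.0109,-12.89,1.07,811.79,4.73,0.0304
grass_pea,T2,0.7807,0.0074,-18.37,0.96,857.33,2.64,0.0221
grass_pea,T3,0.7631,0.0125,-16.27,1.27,903.04,4.72,0.0339
grass_pea,T4,0.7236,0.0134,-18.02,1.62,958.74,5.21,0.0350
grass_pea,T5,0.8359,0.1606,-16.84,4.07,1288.31,36.30,0.0422
grass_pea,T6,0.3194,0.0233,-37.42,6.65,1291.46,9.31,0.0182
lentil,T1,0.6618,0.0098,-17.33,1.31,876.24,4.06,0.0275
lentil,T2,0.6406,0.0102,-16.07,1.19,914.13,4.61,0.0271
lentil,T3,0.5996,0.0106,-23.50,2.06,937.46,4.39,0.0298
lentil,T4,0.5446,0.0125,-21.62,2.98,985.00,6.06,0.0334
lentil,T5,0.6304,0.0820,-13.05,2.46,1232.95,31.55,0.0342
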