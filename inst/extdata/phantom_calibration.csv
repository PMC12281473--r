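sample,gas,o2_fraction,t1_s,t1_sd,r1_mean,r1_sd,n
water,nitrogen,0,4.61,0.11,0.22,0.01,3
water,air,0.21,4.25,0.26,0.24,0.01,3
water,carbogen,0.95,2.97,0.05,0.34,0.01,3
water,oxygen,1.0,2.91,0.05,0.34,0.01,3
corn_oil,nitrogen,0,0.67,0.01,1.50,0.02,3
corn_oil,air,0.21,0.60,0.01,1.66,0.02,3
corn_oil,carbogen,0.95,0.48,0.01,2.10,0.02,3
corn_oil,oxygen,1.0,0.47,0.01,2.14,0.03,3
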