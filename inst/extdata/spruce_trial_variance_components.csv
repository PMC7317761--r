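trait,sigma2_pop,sigma2_fam,sigma2_p,transform
BAI,0.008,0.005,0.302,log
WD,110.689,144.723,1689.941,none
CWT,0.010,0.015,0.179,none
LDr,0.000283,0.000796,0.007,log
LD,0.123,0.204,2.95,none
CWRr,0.004,0.008,0.079,log
CWR,0.004,0.005,0.062,log
Rs_2002,1.363e-9,4.677e-4,0.052,none
Rl_2002,0.00161,0.00347,0.045,none
Rc_2002,0.00303,0.00570,0.066,none
Rr_2002,0.00169,0.00287,0.032,none
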