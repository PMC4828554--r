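variable,mean,sd,mc_error,q2.5,q97.5
(Intercept),-0.117,0.202,0.0081,-0.278,0.173
X1,0.138,0.093,0.0033,-0.041,0.244
X2,0.007,0.048,0.0019,-0.047,0.091
X3,0.011,0.053,0.0020,-0.045,0.102
X4,0.026,0.119,0.0047,-0.141,0.142
X5,-0.044,0.079,0.0033,-0.159,0.067
X6,0.143,0.013,0.0052,0.026,0.258
X7,-0.034,0.091,0.0031,-0.118,0.092
X8,0.093,0.055,0.0018,0.021,0.140
X9,0.077,0.011,0.0004,0.005,0.228
X10,-0.047,0.077,0.0028,-0.127,0.046
X11,0.149,0.024,0.0011,0.012,0.253
X12,0.077,0.181,0.0067,-0.135,0.254
X13,0.039,0.078,0.0025,-0.067,0.146
X14,0.032,0.164,0.0061,-0.100,0.271
X15,0.112,0.009,0.0004,0.062,0.218
X16,0.035,0.242,0.0087,-0.193,0.401
X17,0.018,0.121,0.0034,-0.152,0.124
X18,0.195,0.141,0.0029,-0.109,0.454
X19,0.159,0.026,0.0011,0.028,0.336
X20,-0.013,0.112,0.0039,-0.212,0.098
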