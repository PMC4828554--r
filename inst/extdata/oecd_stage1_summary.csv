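node,mean,sd,mc_error,q2.5,median,q97.5,start,sample
Constant,12.713,1.231,0.045,10.713,11.913,13.113,12000,37500
GDP,7.631,0.226,0.009,6.816,7.126,7.436,12000,37500
Health expenditure,1.625,0.085,0.002,1.323,1.417,1.671,12000,37500
Education,0.932,0.456,0.015,-0.045,10.021,1.524,12000,37500
Tobacco consumption,1.441,0.036,0.001,0.817,1.563,1.971,12000,37500
Alcohol consumption,0.673,0.423,0.007,-0.126,0.871,1.320,12000,37500
Fruit and vegetables consumption,1.273,0.185,0.003,0.871,1.345,1.824,12000,37500
Nitrogen oxide emissions,0.717,0.167,0.002,0.218,0.894,1.023,12000,37500
Time,1.231,0.027,0.001,0.101,1.321,1.444,12000,37500
Lambda,0.128,0.063,0.002,0.071,0.112,0.011,12000,37500
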