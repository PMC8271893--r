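group,variant,fold1,fold2,fold3,fold4,avg,std
elderly,original_avg,0.40,0.33,0.60,0.71,0.55,0.15
elderly,smoothed,0.53,0.80,0.87,0.64,0.75,0.13
elderly,zero_phase,0.60,0.53,0.67,0.36,0.54,0.12
elderly,zero_phase_smoothed,0.53,0.47,0.53,0.64,0.54,0.06
youth,original_avg,0.67,0.60,0.47,0.64,0.59,0.08
youth,smoothed,0.53,0.47,0.47,0.50,0.49,0.03
youth,zero_phase,0.33,0.67,0.60,0.50,0.53,0.13
youth,zero_phase_smoothed,0.73,0.47,0.47,0.86,0.63,0.17
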