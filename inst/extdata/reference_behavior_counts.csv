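group,shape,correct_avg,correct_sd,incorrect_avg,incorrect_sd,error_rate_pct
elderly,triangle,15.2,2.68,5,3.38,24.1
elderly,circle,16.7,2.83,3.7,1.95,18.5
elderly,rectangle,15.9,1.97,3.9,1.51,19.8
elderly,avg,15.93,1.48,4.2,2.28,20.8
youth,triangle,17.1,1.37,2.4,0.8,12.4
youth,circle,16.5,1.80,3.2,1.6,16.2
youth,rectangle,16.8,1.25,3.1,1.6,15.3
youth,avg,16.8,1.48,2.9,1.35,14.6
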