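group,condition,row,N200,P300,N400,P600
elderly,correct,triangle,249,406,498,634
elderly,correct,circle,241,376,490,668
elderly,correct,rectangle,218,411,539,618
elderly,correct,avg,236,398,509,640
elderly,correct,std,13.13,15.48,21.21,20.82
elderly,incorrect,triangle,248,414,510,625
elderly,incorrect,circle,232,420,517,618
elderly,incorrect,rectangle,265,447,541,642
elderly,incorrect,avg,248,427,523,628
elderly,incorrect,std,13.64,14.61,13.20,10.07
youth,correct,triangle,222,432,535,610
youth,correct,circle,203,356,480,595
youth,correct,rectangle,234,400,505,672
youth,correct,avg,220,396,507,626
youth,correct,std,12.55,31.08,22.65,33.27
youth,incorrect,triangle,254,427,487,639
youth,incorrect,circle,236,403,479,617
youth,incorrect,rectangle,266,453,534,681
youth,incorrect,avg,252,427,500,646
youth,incorrect,std,12.50,20.44,24.56,26.80
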