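wave,sex,bmi_mean
1,M,17.71
2,M,19.34
3,M,21.77
4,M,24.23
5,M,26.16
1,F,17.54
2,F,19.35
3,F,20.93
4,F,22.70
5,F,25.02
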