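period,antecedent,consequent,support_antecedent,support_consequent,support,confidence,lift,leverage,conviction
overall,B99,B20+B37,0.34,0.40,0.22,0.65,1.61,0.08,1.69
overall,B20+B37,B99,0.40,0.34,0.22,0.55,1.61,0.08,1.45
overall,B37+B99,B20,0.28,0.53,0.22,0.79,1.51,0.07,2.30
overall,B99,B20,0.34,0.53,0.27,0.79,1.51,0.09,2.30
overall,B20,B99,0.53,0.34,0.27,0.51,1.51,0.09,1.36
overall,B20,B37+B99,0.53,0.28,0.22,0.42,1.51,0.07,1.24
overall,B37+D64,E46+E87,0.34,0.41,0.20,0.59,1.45,0.06,1.45
2019-2020,B20+B37,B99,0.43,0.38,0.24,0.56,1.46,0.08,1.40
2019-2020,B99,B20+B37,0.38,0.43,0.24,0.63,1.46,0.08,1.54
2021-2022,B49+E87,E46,0.25,0.58,0.20,0.80,1.39,0.06,2.14
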