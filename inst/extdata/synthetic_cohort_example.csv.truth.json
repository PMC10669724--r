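{"B0":5.14,"B1":0.1,"B3":0.21,"B4":0.08,"B5":-0.52,"B6":0.1,"B7":0.14,"B8":0.01,"trueModel":"d","crossover":"max","crossover_value":1.55668454273525,"residualSd":0.865,"riskSnp":"rs11629841","riskGenotype":"GT","n":24,"seed":20231027}
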