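label,objective,methods,results,conclusion
objective,20250,1247,24,530
methods,705,20496,397,345
results,210,626,18005,2990
conclusion,102,141,1585,19876
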