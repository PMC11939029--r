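label,objective,methods,results,conclusion
objective,20401,251,129,1447
methods,505,19673,1325,29
results,288,1655,19864,593
conclusion,749,252,386,19982
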