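{"vectors":[0.65255963509747,0.245916528302154,0.702170236136161,0.795157616538464,0.284820789490419,0.554300844279246],"max_concentrations":[1.0393940237943,1.15947901700862],"alpha":1,"beta":0.15}
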