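patient,mode,n_injected,n_identifiable
1,single_energy,66,57
2,dual_energy,52,43
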