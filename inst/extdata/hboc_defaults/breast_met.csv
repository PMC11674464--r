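nodes,p_met
negative,0.01
positive,0.08
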