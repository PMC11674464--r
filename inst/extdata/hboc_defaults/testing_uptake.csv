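cancer,uptake
breast,0.96
ovary,0.95
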