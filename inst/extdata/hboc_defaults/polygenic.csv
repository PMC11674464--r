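organ,hr_per_sd
breast,1.6
ovary,1.3
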