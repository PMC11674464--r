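size_class,p_pos
<=10,0.12
11-20,0.25
21-50,0.45
>50,0.65
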