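sample	stage
t01	1
t02	2
t03	2
t04	3
t05	4
t06	5
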