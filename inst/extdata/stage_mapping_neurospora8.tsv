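sample	stage
t01	1
t02	1
t03	2
t04	2
t05	3
t06	4
t07	5
t08	5
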