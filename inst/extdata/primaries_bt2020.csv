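name,x,y
red,0.708,0.292
green,0.170,0.797
blue,0.131,0.046
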