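name,x,y
red,0.707,0.2834
green,0.106,0.8034
blue,0.1397,0.0399
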