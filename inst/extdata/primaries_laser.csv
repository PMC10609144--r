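name,x,y
red,0.7077,0.2834
green,0.105,0.8181
blue,0.1547,0.0247
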