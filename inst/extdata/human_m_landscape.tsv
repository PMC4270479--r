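genotype	lambda_max	functional
ancestor	560	true
S180A	555	true
Y277F	550	true
T285A	543	true
S180A+Y277F	545	true
S180A+T285A	536	true
Y277F+T285A	534	true
S180A+Y277F+T285A	531	true
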