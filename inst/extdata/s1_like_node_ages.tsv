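node	age_my
root	105
boreoeutheria	90
primates	80
haplorhini	75
anthropoidea	45
catarrhini	30
hominoidea	20
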