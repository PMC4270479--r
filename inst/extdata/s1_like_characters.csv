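taxon,F46T,F49L,T52F,F86L,T93P,A114G,S118T
Human,T,L,F,L,P,G,T
Chimpanzee,T,L,F,L,P,G,T
Gorilla,T,L,F,L,P,G,T
Orangutan,T,L,F,L,P,G,T
Gibbon,T,L,F,L,P,G,T
Macaque,F,L,T,L,P,G,T
Marmoset,F,F,T,L,P,G,S
SquirrelMonkey,F,F,T,L,P,G,S
Tarsier,F,F,T,F,P,G,S
AyeAye,F,F,T,F,T,A,S
Mouse,F,F,T,F,T,A,S
Rat,F,F,T,F,T,A,S
Squirrel,F,F,T,F,T,A,S
GuineaPig,F,F,T,F,T,A,S
Elephant,F,F,T,F,T,A,S
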