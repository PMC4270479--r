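((((((((((Human,Chimpanzee),Gorilla),Orangutan),Gibbon),Macaque),(Marmoset,SquirrelMonkey)),Tarsier),AyeAye),(((Mouse,Rat),Squirrel),GuineaPig)),Elephant);
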