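genotype	lambda_max	functional
ancestor	357	true
F46T	355	true
F49L	354	true
T52F	NF	false
F86L	357	true
T93P	359	true
A114G	358	true
S118T	358	true
F46T+F49L	352	true
F46T+T52F	362	true
F49L+T52F	354	true
F46T+F86L	355	true
F49L+F86L	354	true
T52F+F86L	357	true
F46T+T93P	357	true
F49L+T93P	356	true
T52F+T93P	359	true
F86L+T93P	379	true
F46T+A114G	NF	false
F49L+A114G	355	true
T52F+A114G	358	true
F86L+A114G	358	true
T93P+A114G	380	true
F46T+S118T	356	true
F49L+S118T	363	true
T52F+S118T	358	true
F86L+S118T	358	true
T93P+S118T	360	true
A114G+S118T	359	true
F46T+F49L+T52F	359	true
F46T+F49L+F86L	352	true
F46T+T52F+F86L	362	true
F49L+T52F+F86L	354	true
F46T+F49L+T93P	354	true
F46T+T52F+T93P	364	true
F49L+T52F+T93P	356	true
F46T+F86L+T93P	377	true
F49L+F86L+T93P	376	true
T52F+F86L+T93P	379	true
F46T+F49L+A114G	353	true
F46T+T52F+A114G	363	true
F49L+T52F+A114G	355	true
F46T+F86L+A114G	356	true
F49L+F86L+A114G	355	true
T52F+F86L+A114G	358	true
F46T+T93P+A114G	378	true
F49L+T93P+A114G	377	true
T52F+T93P+A114G	380	true
F86L+T93P+A114G	400	true
F46T+F49L+S118T	361	true
F46T+T52F+S118T	363	true
F49L+T52F+S118T	363	true
F46T+F86L+S118T	356	true
F49L+F86L+S118T	363	true
T52F+F86L+S118T	358	true
F46T+T93P+S118T	358	true
F49L+T93P+S118T	365	true
T52F+T93P+S118T	360	true
F86L+T93P+S118T	380	true
F46T+A114G+S118T	357	true
F49L+A114G+S118T	364	true
T52F+A114G+S118T	359	true
F86L+A114G+S118T	359	true
T93P+A114G+S118T	381	true
F46T+F49L+T52F+F86L	359	true
F46T+F49L+T52F+T93P	361	true
F46T+F49L+F86L+T93P	374	true
F46T+T52F+F86L+T93P	384	true
F49L+T52F+F86L+T93P	376	true
F46T+F49L+T52F+A114G	360	true
F46T+F49L+F86L+A114G	353	true
F46T+T52F+F86L+A114G	363	true
F49L+T52F+F86L+A114G	355	true
F46T+F49L+T93P+A114G	375	true
F46T+T52F+T93P+A114G	385	true
F49L+T52F+T93P+A114G	377	true
F46T+F86L+T93P+A114G	398	true
F49L+F86L+T93P+A114G	397	true
T52F+F86L+T93P+A114G	400	true
F46T+F49L+T52F+S118T	368	true
F46T+F49L+F86L+S118T	361	true
F46T+T52F+F86L+S118T	363	true
F49L+T52F+F86L+S118T	363	true
F46T+F49L+T93P+S118T	363	true
F46T+T52F+T93P+S118T	365	true
F49L+T52F+T93P+S118T	365	true
F46T+F86L+T93P+S118T	378	true
F49L+F86L+T93P+S118T	385	true
T52F+F86L+T93P+S118T	380	true
F46T+F49L+A114G+S118T	362	true
F46T+T52F+A114G+S118T	364	true
F49L+T52F+A114G+S118T	364	true
F46T+F86L+A114G+S118T	357	true
F49L+F86L+A114G+S118T	364	true
T52F+F86L+A114G+S118T	359	true
F46T+T93P+A114G+S118T	379	true
F49L+T93P+A114G+S118T	386	true
T52F+T93P+A114G+S118T	381	true
F86L+T93P+A114G+S118T	401	true
F46T+F49L+T52F+F86L+T93P	381	true
F46T+F49L+T52F+F86L+A114G	360	true
F46T+F49L+T52F+T93P+A114G	382	true
F46T+F49L+F86L+T93P+A114G	395	true
F46T+T52F+F86L+T93P+A114G	405	true
F49L+T52F+F86L+T93P+A114G	397	true
F46T+F49L+T52F+F86L+S118T	368	true
F46T+F49L+T52F+T93P+S118T	370	true
F46T+F49L+F86L+T93P+S118T	383	true
F46T+T52F+F86L+T93P+S118T	385	true
F49L+T52F+F86L+T93P+S118T	385	true
F46T+F49L+T52F+A114G+S118T	369	true
F46T+F49L+F86L+A114G+S118T	362	true
F46T+T52F+F86L+A114G+S118T	364	true
F49L+T52F+F86L+A114G+S118T	364	true
F46T+F49L+T93P+A114G+S118T	384	true
F46T+T52F+T93P+A114G+S118T	386	true
F49L+T52F+T93P+A114G+S118T	386	true
F46T+F86L+T93P+A114G+S118T	399	true
F49L+F86L+T93P+A114G+S118T	406	true
T52F+F86L+T93P+A114G+S118T	401	true
F46T+F49L+T52F+F86L+T93P+A114G	402	true
F46T+F49L+T52F+F86L+T93P+S118T	390	true
F46T+F49L+T52F+F86L+A114G+S118T	369	true
F46T+F49L+T52F+T93P+A114G+S118T	391	true
F46T+F49L+F86L+T93P+A114G+S118T	404	true
F46T+T52F+F86L+T93P+A114G+S118T	406	true
F49L+T52F+F86L+T93P+A114G+S118T	406	true
F46T+F49L+T52F+F86L+T93P+A114G+S118T	411	true
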