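# PEPMASS=913.9 CHARGE=2- (negative mode, ion trap MS2)
145.1 40
161.0 40
163.1 40
179.1 40
202.1 40
220.1 40
350.1 40
364.1 40
368.2 40
382.1 40
424.1 40
508.1 100
526.2 40
544.2 40
553.2 40
571.2 40
729.3 100
1256.4 40
1274.5 40
1283.5 40
1301.5 40
1445.5 40
1459.5 40
1463.6 40
1477.5 40
1607.6 40
1625.6 40
1648.6 40
1664.6 40
1666.6 40
1682.6 40
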