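glycan_id,glycan_class,mass_mh,mass_m2h,composition,motif
1205.0,N,2411.0,1205.0,(Hex)5(HexNAc)5(dHex)1(Neu5Ac)2,sialyl-LacdiNAc/LacNAc
937.3,N,1875.6,937.3,(Hex)7(HexNAc)3(dHex)1(Neu5Ac)1,hybrid monosialylated
1059.4,N,2119.8,1059.4,(Hex)4(HexNAc)5(dHex)1(Neu5Ac)1,sialyl-LacdiNAc
856.3,N,1713.6,856.3,(Hex)6(HexNAc)3(dHex)1(Neu5Ac)1,hybrid monosialylated
994.9,N,1990.8,994.9,(Hex)5(HexNAc)5(dHex)1,bisecting biantennary
739.3,N,1479.6,739.3,(Hex)3(HexNAc)4(dHex)1,agalactosylated biantennary
1038.9,N,2078.8,1038.9,(Hex)5(HexNAc)4(dHex)1(Neu5Ac)1,monosialylated biantennary
1286.0,N,2573.0,1286.0,(Hex)5(HexNAc)5(dHex)1(Neu5Ac)2,bisecting sialylated biantennary
1079.9,N,2160.8,1079.9,(Hex)4(HexNAc)6(Neu5Ac)1,sialyl-LacdiNAc
1294.0,N,2589.0,1294.0,(Hex)6(HexNAc)5(Neu5Ac)3,branched triantennary
1148.5,N,2298.0,1148.5,(Hex)6(HexNAc)5(dHex)1(Neu5Ac)1,branched triantennary
913.9,N,1828.8,913.9,(Hex)4(HexNAc)5(dHex)1,bisecting/LacdiNAc isomers
945.3,N,1891.6,945.3,(Hex)6(HexNAc)3(Neu5Ac)1,hybrid monosialylated
1221.5,N,2444.0,1221.5,(Hex)6(HexNAc)5(Neu5Ac)2,branched triantennary
1440.0,N,2881.0,1440.0,(Hex)7(HexNAc)6(Neu5Ac)2,branched tetraantennary
1550.1,N,3101.2,1550.1,(Hex)7(HexNAc)6(Neu5Ac)3,branched tetraantennary
749.3,O,749.3,,(Hex)1(HexNAc)2(Neu5Ac)1,sialylated core 2
755.3,O,755.3,,(Hex)2(HexNAc)2(dHex)1,fucosylated core 2
1040.5,O,1040.5,,(Hex)2(HexNAc)2(Neu5Ac)1,sialylated core 2
1331.5,O,1331.5,,(Hex)2(HexNAc)2(Neu5Ac)2,disialylated core 2
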