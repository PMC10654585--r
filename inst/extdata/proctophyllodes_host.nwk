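((Agelaius_phoeniceus,(Molothrus_ater,Molothrus_bonariensis)),((Ammodramus_humeralis,Zonotrichia_capensis),(Cardinalis_cardinalis,Piranga_flava)));
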