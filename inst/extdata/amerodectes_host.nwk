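(((Agelaius_phoeniceus,(Molothrus_ater,Molothrus_bonariensis)),(Cardinalis_cardinalis,Zonotrichia_capensis)),((Sicalis_flaveola,Sicalis_luteola),(Tangara_sayaca,Thraupis_episcopus)));
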