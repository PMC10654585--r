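((Agelaius_phoeniceus,Molothrus_bonariensis),((Sicalis_flaveola,Sicalis_luteola),Tangara_sayaca));
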