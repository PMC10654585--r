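Trouessartia_sicaliae_SF	Sicalis_flaveola
Trouessartia_sicaliae_MB	Molothrus_bonariensis
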