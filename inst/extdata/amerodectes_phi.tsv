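Amerodectes_tretiakae	Molothrus_ater
Amerodectes_molothrus	Molothrus_bonariensis
Amerodectes_sp_Sicalis	Sicalis_flaveola
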