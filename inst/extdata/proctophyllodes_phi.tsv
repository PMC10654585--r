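Proctophyllodes_sp_M_ater	Molothrus_ater
Proctophyllodes_molothrus	Molothrus_bonariensis
Proctophyllodes_outgroup	Zonotrichia_capensis
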