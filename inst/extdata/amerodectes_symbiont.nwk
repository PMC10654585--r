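((Amerodectes_molothrus,Amerodectes_tretiakae),Amerodectes_sp_Sicalis);
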