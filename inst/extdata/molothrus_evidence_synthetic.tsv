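taxon	found_on_focal_host	found_on_foster_hosts	ecological_group	sister_taxon_host	distance_to_nearest_foster_mite
Amerodectes molothrus	TRUE	FALSE	vane	Molothrus ater	0.095
Mesalgoides sp. 1	TRUE	FALSE	vane	NA	NA
Proctophyllodes molothrus	TRUE	FALSE	vane	Molothrus ater	0.055
Trouessartia sp. 6	TRUE	FALSE	vane	NA	NA
Xolalgoides sp. 1	TRUE	FALSE	vane	NA	NA
Amerodectes bilineatus	TRUE	TRUE	vane	NA	NA
Analges sp. 1	TRUE	TRUE	vane	NA	NA
Analges sp. 5	TRUE	TRUE	vane	NA	NA
Analges sp. 6	TRUE	TRUE	vane	NA	NA
Analges ticotico	TRUE	TRUE	vane	NA	NA
Mesalgoides sp. 2	TRUE	TRUE	vane	NA	NA
Mesalgoides sp. 3	TRUE	TRUE	vane	NA	NA
Platyacarus sp.	TRUE	TRUE	vane	NA	NA
Proctophyllodes aff. atyeoi	TRUE	TRUE	vane	NA	NA
Proctophyllodes cf. thraupis	TRUE	TRUE	vane	NA	NA
Proctophyllodes sp. 16	TRUE	TRUE	vane	NA	NA
Proctophyllodes sp. 4	TRUE	TRUE	vane	NA	NA
Proctophyllodes sp. 5	TRUE	TRUE	vane	NA	NA
Proctophyllodes carmenmirandae	TRUE	TRUE	vane	NA	NA
Trouessartia aff. megaplax	TRUE	TRUE	vane	NA	NA
Trouessartia capensis	TRUE	TRUE	vane	NA	NA
Trouessartia sp. 7	TRUE	TRUE	vane	NA	NA
Trouessartia cf. sicaliae	TRUE	TRUE	vane	NA	0.036
Xolalgoides sp. 2	TRUE	TRUE	vane	NA	NA
Dermationidae gen. sp.	TRUE	FALSE	quill_skin	NA	NA
Dermoglyphus cf. passerinus	TRUE	FALSE	quill_skin	NA	NA
Microlichus cf. americanus	TRUE	FALSE	quill_skin	NA	NA
Metamicrolichus cf. phasianus	TRUE	FALSE	quill_skin	NA	NA
Strelkoviacarus brasiliensis	TRUE	FALSE	quill_skin	NA	NA
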