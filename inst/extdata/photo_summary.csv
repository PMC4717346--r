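study_area,species,grid_area,n_sites_detected,n_photographs,n_sites_total
WS,bobcat,urbanized,20,112,20
WS,bobcat,wildland,18,73,20
WS,bobcat,total,38,185,40
WS,puma,urbanized,11,39,20
WS,puma,wildland,12,41,20
WS,puma,total,23,80,40
FR,bobcat,urbanized,15,81,20
FR,bobcat,wildland,17,69,20
FR,bobcat,total,32,150,40
FR,puma,urbanized,19,50,20
FR,puma,wildland,17,46,20
FR,puma,total,36,96,40
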