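study_area,grid,delta_hat,ci_low,ci_high
WS,urbanized,0.93,0.86,0.97
WS,wildland,0.77,0.62,0.89
FR,urbanized,0.87,0.77,0.94
FR,wildland,0.86,0.76,0.94
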