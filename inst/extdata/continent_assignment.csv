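continent,source_region
NorthAmerica,UnitedStates
SouthAmerica,Uruguay
Africa,Libya
Oceania,NewZealand
Europe,EU28
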