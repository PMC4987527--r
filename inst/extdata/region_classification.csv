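region,continent,development
Libya,Africa,developing
UnitedStates,NorthAmerica,developed
Uruguay,SouthAmerica,developing
China,Asia,developing
Iran,Asia,developing
Japan,Asia,developed
Taiwan,Asia,developing
EU28,Europe,developed
Serbia,Europe,developing
NewZealand,Oceania,developed
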