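region,year,sex,cases
Libya,2015,male,198
Libya,2015,female,95
Libya,2040,male,433
Libya,2040,female,202
UnitedStates,2015,male,12656
UnitedStates,2015,female,9179
UnitedStates,2040,male,17184
UnitedStates,2040,female,12122
Uruguay,2015,male,146
Uruguay,2015,female,61
Uruguay,2040,male,193
Uruguay,2040,female,76
China,2015,male,12261
China,2015,female,8068
China,2040,male,17281
China,2040,female,12453
Iran,2015,male,774
Iran,2015,female,635
Iran,2040,male,1699
Iran,2040,female,1293
Japan,2015,male,3241
Japan,2015,female,2625
Japan,2040,male,3558
Japan,2040,female,2873
Taiwan,2015,male,345
Taiwan,2015,female,277
Taiwan,2040,male,432
Taiwan,2040,female,364
EU28,2015,male,15960
EU28,2015,female,13248
EU28,2040,male,19320
EU28,2040,female,15704
Serbia,2015,male,74
Serbia,2015,female,52
Serbia,2040,male,69
Serbia,2040,female,48
NewZealand,2015,male,154
NewZealand,2015,female,111
NewZealand,2040,male,226
NewZealand,2040,female,165
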