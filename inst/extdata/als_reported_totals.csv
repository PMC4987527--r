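scope,year,group,cases
ten_region,2015,male,45810
ten_region,2015,female,34352
ten_region,2015,total,80162
ten_region,2040,male,60394
ten_region,2040,female,45299
ten_region,2040,total,105693
global,2015,total,222801
global,2040,total,376674
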