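machine_id,valid_from,offset,slope,offset_sd,slope_sd
A,2007-10-31,25,1000,15,55
A,2011-07-29,12,992,15,41
A,2012-07-01,8,970,4,12
B,2010-01-14,35,982,9,27
B,2011-04-01,15,962,14,33
B,2012-07-01,10,940,5,10
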