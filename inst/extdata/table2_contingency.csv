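domain,Y,M,No
medical,1,2,2
biology,3,3,2
general,3,5,13
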