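bpm0/module1	P01A01	P01A02	P01A03	P01A04
bpm0/module2	P01B01	P01B02	P01B03	P01B04
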