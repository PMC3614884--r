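P01A01	GO:0006891	intra-Golgi vesicle-mediated transport
P01A02	GO:0006891	intra-Golgi vesicle-mediated transport
P01A03	GO:0006891	intra-Golgi vesicle-mediated transport
P01A04	GO:0006891	intra-Golgi vesicle-mediated transport
P01B01	GO:0006623	protein targeting to vacuole
P01B02	GO:0006623	protein targeting to vacuole
P01B03	GO:0006623	protein targeting to vacuole
P01B04	GO:0006623	protein targeting to vacuole
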