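BG001	BG004	0.085483042312845633
BG001	BG005	-0.057837041896185437
BG001	BG007	0.049636153903015234
BG002	BG003	-0.076005793061178828
BG002	BG008	-0.034138627039942936
BG002	BG010	-0.21023291204778013
BG002	BG012	-0.030170228136889549
BG003	BG009	-0.12723834421812039
BG003	BG010	-0.027966610980922908
BG003	BG012	-0.0204097320819576
BG004	BG011	-0.022561418551735529
BG005	BG008	0.034702845202209905
BG007	BG011	0.0032367842597923278
BG009	BG011	0.041353128967179839
BG010	BG011	-0.015534847662537869
BG010	BG012	0.09734853924830475
P01A01	P01A02	0.91591445192137011
P01A01	P01A03	1.1384359343478585
P01A01	P01A04	0.87445081373723332
P01A01	P01B01	-1.1080392600027391
P01A01	P01B02	-1.0597313094712926
P01A01	P01B03	-0.90994880546667489
P01A01	P01B04	-0.91809910697378483
P01A02	P01A03	1.0070142766427326
P01A02	P01A04	1.1711440872702372
P01A02	P01B01	-1.0157534356106883
P01A02	P01B02	-1.2183966760091585
P01A02	P01B03	-0.90581306061322553
P01A02	P01B04	-1.0293481848702453
P01A03	P01A04	0.93970920185453333
P01A03	P01B01	-1.1071760039877916
P01A03	P01B02	-0.9759182744063305
P01A03	P01B03	-0.85320380965802978
P01A03	P01B04	-0.85814109275140527
P01A04	P01B01	-1.0138986140549846
P01A04	P01B02	-1.025935540673425
P01A04	P01B03	-0.92932389104420876
P01A04	P01B04	-0.85012261725935134
P01B01	P01B02	0.95278336148330545
P01B01	P01B03	0.93646286874757168
P01B01	P01B04	0.97142263651338467
P01B02	P01B03	1.0138108224803923
P01B02	P01B04	1.1227630343853461
P01B03	P01B04	0.91982205453471755
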