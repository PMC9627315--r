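label	x_mm	y_mm	z_mm
S01	14.7361759441	31.9383391597	82.8419435447
S02	48.2619161891	29.6919476701	69.9226407490
S03	73.7643544947	21.0868656065	47.0549052159
S04	9.3396996072	61.5496862265	64.9954316600
S05	42.7306043967	60.1167065653	51.5759346947
S06	68.3938054968	50.6977529172	29.1894710265
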