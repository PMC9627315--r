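label	x_mm	y_mm	z_mm
D01	15.0674751720	26.5074524005	84.6777784261
D02	37.5263795223	25.7086982552	77.6584423870
D03	57.9087340276	21.9614635875	65.3013984568
D04	73.7860602315	15.7121890132	49.0789611944
D05	12.6657559120	48.0921534505	75.0114884779
D06	35.3134149878	47.7745290052	67.6058954547
D07	55.9456402934	43.9823670187	55.0966126327
D08	72.1112215082	37.1661953027	38.9698044556
D09	7.8994703245	65.6994521079	61.0014783535
D10	30.1914864551	65.8557230481	53.3994184185
D11	50.5816028607	62.1090263389	41.0362071746
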