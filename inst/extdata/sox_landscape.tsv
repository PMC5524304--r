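# lineage: human=outgroup mouse=outgroup coelacanth=outgroup spotted_gar=outgroup elephant_shark=outgroup zebrafish=teleost cavefish=teleost cod=teleost tilapia=teleost medaka=teleost platyfish=teleost tetraodon=teleost fugu=teleost stickleback=teleost salmon=salmonid_teleost trout=salmonid_teleost
gene	origin	human	mouse	coelacanth	spotted_gar	elephant_shark	zebrafish	cavefish	cod	tilapia	medaka	platyfish	tetraodon	fugu	stickleback	salmon	trout
sox1	WGD_duplicate	1	1	1	1	1	2	1	1	1	2	1	1	1	1	3	3
sox2	singleton	1	1	1	1	1	1	1	1	1	1	1	1	1	1	3	2
sox3	singleton	1	1	1	1	1	1	1	1	1	1	1	1	1	1	3	2
sox4	WGD_duplicate	1	1	1	1	1	2	2	2	2	2	2	2	2	2	3	3
sox5	singleton	1	1	1	1	1	1	1	1	1	1	1	1	1	1	3	3
sox6	WGD_duplicate	1	1	1	1	1	2	1	1	1	1	1	1	1	1	3	3
sox7	singleton	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
sox8	WGD_duplicate	1	1	1	1	1	2	1	1	1	1	2	1	1	1	3	3
sox9	WGD_duplicate	1	1	1	1	1	2	2	2	2	2	2	2	2	2	3	3
sox10	WGD_duplicate	1	1	1	1	1	1	0	1	1	2	2	1	1	1	3	3
sox11	WGD_duplicate	1	1	1	1	1	2	1	1	1	1	2	1	1	1	3	3
sox12	singleton	1	1	1	1	1	1	1	0	0	0	0	0	0	0	1	1
sox13	singleton	1	1	1	1	1	1	1	1	1	1	1	1	1	1	3	3
sox14	WGD_duplicate	1	1	1	1	1	2	1	1	1	1	1	1	1	1	3	3
sox17	SSD_duplicate	1	1	1	1	1	2	2	2	2	2	2	2	2	2	3	3
sox18	singleton	1	1	1	1	1	1	1	1	1	1	1	1	1	1	3	3
sox19	WGD_duplicate	1	1	1	1	0	2	1	1	1	1	1	1	1	1	3	3
sox21	WGD_duplicate	1	1	1	1	1	2	2	1	1	1	1	1	1	1	3	3
sox30	singleton	1	1	1	1	1	0	0	1	1	0	1	0	0	0	1	1
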