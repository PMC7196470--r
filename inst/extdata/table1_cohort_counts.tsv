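set	category	group	count
EPILEPSY	C	COMPLETE	851
CTRL1	C	COMPLETE	858
CTRL2	C	COMPLETE	278
CTRL3	C	COMPLETE	707
CTRL4	C	COMPLETE	702
ID	C	COMPLETE	1572
EPILEPSY	D	COMPLETE	1876
CTRL1	D	COMPLETE	1778
CTRL2	D	COMPLETE	497
CTRL3	D	COMPLETE	1378
CTRL4	D	COMPLETE	1603
ID	D	COMPLETE	3172
EPILEPSY	E	COMPLETE	2455
CTRL1	E	COMPLETE	2608
CTRL2	E	COMPLETE	765
CTRL3	E	COMPLETE	2165
CTRL4	E	COMPLETE	2291
ID	E	COMPLETE	4919
EPILEPSY	C	EXTREME	337
CTRL1	C	EXTREME	305
CTRL2	C	EXTREME	130
CTRL3	C	EXTREME	270
CTRL4	C	EXTREME	247
ID	C	EXTREME	582
EPILEPSY	D	EXTREME	662
CTRL1	D	EXTREME	626
CTRL2	D	EXTREME	218
CTRL3	D	EXTREME	501
CTRL4	D	EXTREME	579
ID	D	EXTREME	1132
EPILEPSY	E	EXTREME	888
CTRL1	E	EXTREME	893
CTRL2	E	EXTREME	327
CTRL3	E	EXTREME	798
CTRL4	E	EXTREME	824
ID	E	EXTREME	1739
EPILEPSY	C	INTERMEDIATE	161
CTRL1	C	INTERMEDIATE	176
CTRL2	C	INTERMEDIATE	49
CTRL3	C	INTERMEDIATE	147
CTRL4	C	INTERMEDIATE	131
ID	C	INTERMEDIATE	355
EPILEPSY	D	INTERMEDIATE	335
CTRL1	D	INTERMEDIATE	371
CTRL2	D	INTERMEDIATE	83
CTRL3	D	INTERMEDIATE	300
CTRL4	D	INTERMEDIATE	331
ID	D	INTERMEDIATE	708
EPILEPSY	E	INTERMEDIATE	481
CTRL1	E	INTERMEDIATE	546
CTRL2	E	INTERMEDIATE	140
CTRL3	E	INTERMEDIATE	467
CTRL4	E	INTERMEDIATE	473
ID	E	INTERMEDIATE	1071
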