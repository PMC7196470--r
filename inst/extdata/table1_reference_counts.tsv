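set	maf_threshold	count
EPILEPSY	0.01	300155
CTRL1	0.01	299750
CTRL2	0.01	90285
CTRL3	0.01	260659
CTRL4	0.01	261763
ID	0.01	557769
EPILEPSY	0.05	556293
CTRL1	0.05	641440
CTRL2	0.05	185549
CTRL3	0.05	513655
CTRL4	0.05	565998
ID	0.05	1099721
EPILEPSY	0.1	805686
CTRL1	0.1	950857
CTRL2	0.1	260406
CTRL3	0.1	812452
CTRL4	0.1	853276
ID	0.1	1707615
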