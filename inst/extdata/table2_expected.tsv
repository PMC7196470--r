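target_set	control_set	category	group	overrep_pct	p_display	p_ceiling	bold
EPILEPSY	CTRL1	C	COMPLETE	-1	0.846	0	0
EPILEPSY	CTRL1	C	EXTREME	10	0.221	0	0
EPILEPSY	CTRL1	C	INTERMEDIATE	9	0.414	0	0
EPILEPSY	CTRL1	D	COMPLETE	22	3e-04	1	1
EPILEPSY	CTRL1	D	EXTREME	22	5e-04	1	0
EPILEPSY	CTRL1	D	INTERMEDIATE	4	0.598	0	0
EPILEPSY	CTRL1	E	COMPLETE	11	3e-04	1	1
EPILEPSY	CTRL1	E	EXTREME	17	0.001	0	0
EPILEPSY	CTRL1	E	INTERMEDIATE	4	0.552	0	0
EPILEPSY	CTRL2	C	COMPLETE	-8	0.229	0	0
EPILEPSY	CTRL2	C	EXTREME	-22	0.017	0	0
EPILEPSY	CTRL2	C	INTERMEDIATE	-1	0.941	0	0
EPILEPSY	CTRL2	D	COMPLETE	26	3e-04	1	1
EPILEPSY	CTRL2	D	EXTREME	1	0.904	0	0
EPILEPSY	CTRL2	D	INTERMEDIATE	35	0.016	0	0
EPILEPSY	CTRL2	E	COMPLETE	4	0.388	0	0
EPILEPSY	CTRL2	E	EXTREME	-12	0.044	0	0
EPILEPSY	CTRL2	E	INTERMEDIATE	11	0.283	0	0
EPILEPSY	CTRL3	C	COMPLETE	5	0.387	0	0
EPILEPSY	CTRL3	C	EXTREME	8	0.329	0	0
EPILEPSY	CTRL3	C	INTERMEDIATE	-5	0.69	0	0
EPILEPSY	CTRL3	D	COMPLETE	26	3e-04	1	1
EPILEPSY	CTRL3	D	EXTREME	22	0.001	0	0
EPILEPSY	CTRL3	D	INTERMEDIATE	3	0.721	0	0
EPILEPSY	CTRL3	E	COMPLETE	14	3e-04	1	1
EPILEPSY	CTRL3	E	EXTREME	12	0.019	0	0
EPILEPSY	CTRL3	E	INTERMEDIATE	4	0.581	0	0
EPILEPSY	CTRL4	C	COMPLETE	6	0.285	0	0
EPILEPSY	CTRL4	C	EXTREME	19	0.038	0	0
EPILEPSY	CTRL4	C	INTERMEDIATE	7	0.597	0	0
EPILEPSY	CTRL4	D	COMPLETE	19	3e-04	1	1
EPILEPSY	CTRL4	D	EXTREME	16	0.008	0	0
EPILEPSY	CTRL4	D	INTERMEDIATE	3	0.727	0	0
EPILEPSY	CTRL4	E	COMPLETE	13	3e-04	1	1
EPILEPSY	CTRL4	E	EXTREME	14	0.007	0	0
EPILEPSY	CTRL4	E	INTERMEDIATE	8	0.257	0	0
EPILEPSY	CTRL1-4	C	COMPLETE	2	0.677	0	0
EPILEPSY	CTRL1-4	C	EXTREME	8	0.245	0	0
EPILEPSY	CTRL1-4	C	INTERMEDIATE	-3	0.785	0	0
EPILEPSY	CTRL1-4	D	COMPLETE	22	3e-04	1	1
EPILEPSY	CTRL1-4	D	EXTREME	18	3e-04	1	1
EPILEPSY	CTRL1-4	D	INTERMEDIATE	6	0.374	0	0
EPILEPSY	CTRL1-4	E	COMPLETE	12	3e-04	1	1
EPILEPSY	CTRL1-4	E	EXTREME	12	0.005	0	0
EPILEPSY	CTRL1-4	E	INTERMEDIATE	6	0.292	0	0
ID	CTRL1	C	COMPLETE	-2	0.718	0	0
ID	CTRL1	C	EXTREME	3	0.75	0	0
ID	CTRL1	C	INTERMEDIATE	8	0.042	0	0
ID	CTRL1	D	COMPLETE	4	0.184	0	0
ID	CTRL1	D	EXTREME	5	0.288	0	0
ID	CTRL1	D	INTERMEDIATE	11	0.101	0	0
ID	CTRL1	E	COMPLETE	5	0.045	0	0
ID	CTRL1	E	EXTREME	8	0.051	0	0
ID	CTRL1	E	INTERMEDIATE	9	0.097	0	0
ID	CTRL2	C	COMPLETE	-8	0.178	0	0
ID	CTRL2	C	EXTREME	-28	0.001	0	0
ID	CTRL2	C	INTERMEDIATE	17	0.315	0	0
ID	CTRL2	D	COMPLETE	8	0.127	0	0
ID	CTRL2	D	EXTREME	-12	0.073	0	0
ID	CTRL2	D	INTERMEDIATE	44	0.002	0	0
ID	CTRL2	E	COMPLETE	-2	0.612	0	0
ID	CTRL2	E	EXTREME	-19	0.001	0	0
ID	CTRL2	E	INTERMEDIATE	17	0.092	0	0
ID	CTRL3	C	COMPLETE	4	0.405	0	0
ID	CTRL3	C	EXTREME	1	0.94	0	0
ID	CTRL3	C	INTERMEDIATE	13	0.231	0	0
ID	CTRL3	D	COMPLETE	8	0.025	0	0
ID	CTRL3	D	EXTREME	6	0.326	0	0
ID	CTRL3	D	INTERMEDIATE	10	0.166	0	0
ID	CTRL3	E	COMPLETE	8	0.003	0	0
ID	CTRL3	E	EXTREME	4	0.407	0	0
ID	CTRL3	E	INTERMEDIATE	9	0.12	0	0
ID	CTRL4	C	COMPLETE	5	0.28	0	0
ID	CTRL4	C	EXTREME	11	0.193	0	0
ID	CTRL4	C	INTERMEDIATE	27	0.02	0	0
ID	CTRL4	D	COMPLETE	2	0.561	0	0
ID	CTRL4	D	EXTREME	1	0.918	0	0
ID	CTRL4	D	INTERMEDIATE	10	0.159	0	0
ID	CTRL4	E	COMPLETE	7	0.006	0	0
ID	CTRL4	E	EXTREME	5	0.216	0	0
ID	CTRL4	E	INTERMEDIATE	13	0.025	0	0
ID	CTRL1-4	C	COMPLETE	1	0.784	0	0
ID	CTRL1-4	C	EXTREME	0	1	0	0
ID	CTRL1-4	C	INTERMEDIATE	15	0.041	0	0
ID	CTRL1-4	D	COMPLETE	5	0.045	0	0
ID	CTRL1-4	D	EXTREME	2	0.599	0	0
ID	CTRL1-4	D	INTERMEDIATE	13	0.011	0	0
ID	CTRL1-4	E	COMPLETE	6	0.002	0	0
ID	CTRL1-4	E	EXTREME	3	0.32	0	0
ID	CTRL1-4	E	INTERMEDIATE	11	0.008	0	0
CTRL1	CTRL3	C	COMPLETE	6	0.298	0	0
CTRL1	CTRL3	C	EXTREME	-2	0.835	0	0
CTRL1	CTRL3	C	INTERMEDIATE	4	0.738	0	0
CTRL1	CTRL3	D	COMPLETE	3	0.37	0	0
CTRL1	CTRL3	D	EXTREME	0	1	0	0
CTRL1	CTRL3	D	INTERMEDIATE	-1	0.908	0	0
CTRL1	CTRL3	E	COMPLETE	3	0.323	0	0
CTRL1	CTRL3	E	EXTREME	-4	0.367	0	0
CTRL1	CTRL3	E	INTERMEDIATE	0	1	0	0
CTRL1	CTRL4	C	COMPLETE	7	0.204	0	0
CTRL1	CTRL4	C	EXTREME	8	0.393	0	0
CTRL1	CTRL4	C	INTERMEDIATE	17	0.17	0	0
CTRL1	CTRL4	D	COMPLETE	-2	0.535	0	0
CTRL1	CTRL4	D	EXTREME	-5	0.419	0	0
CTRL1	CTRL4	D	INTERMEDIATE	-1	0.91	0	0
CTRL1	CTRL4	E	COMPLETE	2	0.465	0	0
CTRL1	CTRL4	E	EXTREME	-3	0.578	0	0
CTRL1	CTRL4	E	INTERMEDIATE	4	0.594	0	0
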