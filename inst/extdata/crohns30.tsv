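id	raf	grr	a	ve
v01	0.018	3.99	0.504	.0090
v02	0.533	1.28	0.098	.0048
v03	0.425	1.25	0.083	.0034
v04	0.899	1.31	0.135	.0033
v05	0.387	1.25	0.083	.0032
v06	0.152	1.35	0.106	.0029
v07	0.677	1.22	0.080	.0028
v08	0.463	1.21	0.071	.0025
v09	0.478	1.20	0.067	.0023
v10	0.678	1.20	0.072	.0022
v11	0.780	1.21	0.079	.0022
v12	0.221	1.25	0.079	.0022
v13	0.933	2.50	0.130	.0021
v14	0.125	1.32	0.097	.0021
v15	0.565	1.18	0.062	.0019
v16	0.565	1.18	0.062	.0019
v17	0.697	1.18	0.064	.0017
v18	0.271	1.20	0.065	.0016
v19	0.090	1.33	0.099	.0016
v20	0.243	1.19	0.061	.0014
v21	0.386	1.16	0.053	.0013
v22	0.289	1.17	0.055	.0013
v23	0.345	1.16	0.053	.0013
v24	0.682	1.14	0.049	.0010
v25	0.389	1.13	0.043	.0009
v26	0.473	1.12	0.040	.0008
v27	0.348	1.12	0.040	.0007
v28	0.017	1.54	0.149	.0007
v29	0.708	1.11	0.038	.0006
v30	0.619	1.08	0.027	.0004
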