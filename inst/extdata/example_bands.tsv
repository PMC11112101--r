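region	subject	band_label	frequency_hz	magnitude_au	area_hz	bandwidth_hz
csf	volunteer_2	Band 1	0.318	0.565	0.026	0.056
csf	volunteer_2	Band 3	0.822	0.206	0.012	0.065
csf	volunteer_2	Band 4	1.151	2.435	0.142	0.066
csf	volunteer_3	Band 1	0.269	0.597	0.028	0.056
csf	volunteer_3	Band 2	0.516	0.082	0.003	0.043
csf	volunteer_3	Band 4	1.312	1.507	0.115	0.085
csf	volunteer_4	Band 1	0.387	1.197	0.054	0.057
csf	volunteer_4	Band 3	0.763	0.496	0.039	0.080
csf	volunteer_4	Band 4	1.151	2.048	0.169	0.103
csf	volunteer_5	Band 1	0.333	0.162	0.006	0.043
csf	volunteer_5	Band 3	0.806	0.119	0.006	0.072
csf	volunteer_5	Band 4	1.129	1.374	0.095	0.068
csf	volunteer_6	Band 1	0.247	0.450	0.021	0.053
csf	volunteer_6	Band 2	0.484	0.073	0.005	0.070
csf	volunteer_6	Band 3	0.914	0.128	0.008	0.074
csf	volunteer_6	Band 4	1.226	1.369	0.075	0.068
whole_brain	volunteer_2	Band 1	0.307	0.421	0.020	0.057
whole_brain	volunteer_2	Band 4	1.151	0.961	0.056	0.065
whole_brain	volunteer_3	Band 1	0.269	0.477	0.022	0.055
whole_brain	volunteer_3	Band 4	1.301	0.828	0.067	0.103
whole_brain	volunteer_4	Band 1	0.387	0.769	0.035	0.056
whole_brain	volunteer_4	Band 3	0.763	0.208	0.016	0.084
whole_brain	volunteer_4	Band 4	1.151	0.977	0.094	0.107
whole_brain	volunteer_5	Band 1	0.333	0.070	0.002	0.028
whole_brain	volunteer_5	Band 3	0.806	0.051	0.003	0.066
whole_brain	volunteer_5	Band 4	1.129	0.840	0.058	0.069
whole_brain	volunteer_6	Band 1	0.247	0.354	0.016	0.054
whole_brain	volunteer_6	Band 2	0.516	0.050	0.002	0.057
whole_brain	volunteer_6	Band 3	0.914	0.045	0.003	0.066
whole_brain	volunteer_6	Band 4	1.226	0.715	0.039	0.068
cgm	volunteer_2	Band 1	0.307	0.453	0.021	0.055
cgm	volunteer_2	Band 4	1.151	0.781	0.046	0.065
cgm	volunteer_3	Band 1	0.269	0.510	0.024	0.054
cgm	volunteer_3	Band 4	1.301	0.735	0.059	0.076
cgm	volunteer_4	Band 1	0.387	0.647	0.031	0.052
cgm	volunteer_4	Band 3	0.774	0.177	0.016	0.088
cgm	volunteer_4	Band 4	1.161	0.882	0.066	0.089
cgm	volunteer_5	Band 1	0.344	0.077	0.002	0.035
cgm	volunteer_5	Band 4	1.129	0.824	0.045	0.067
cgm	volunteer_6	Band 1	0.247	0.315	0.011	0.050
cgm	volunteer_6	Band 2	0.516	0.082	0.004	0.057
cgm	volunteer_6	Band 4	1.226	0.711	0.040	0.066
cwm	volunteer_2	Band 1	0.307	0.315	0.015	0.055
cwm	volunteer_2	Band 4	1.162	0.363	0.016	0.061
cwm	volunteer_3	Band 1	0.269	0.382	0.018	0.054
cwm	volunteer_3	Band 4	1.301	0.253	0.018	0.090
cwm	volunteer_4	Band 1	0.387	0.423	0.025	0.056
cwm	volunteer_4	Band 3	0.774	0.067	0.004	0.069
cwm	volunteer_4	Band 4	1.161	0.376	0.030	0.081
cwm	volunteer_5	Band 1	0.344	0.157	0.006	0.045
cwm	volunteer_5	Band 4	1.140	0.501	0.028	0.063
cwm	volunteer_6	Band 1	0.247	0.230	0.011	0.055
cwm	volunteer_6	Band 4	1.226	0.391	0.022	0.067
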