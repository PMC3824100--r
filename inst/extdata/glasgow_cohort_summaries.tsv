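variable	mean_a	sd_a	n_a	mean_b	sd_b	n_b
Age (years)	51.18	8.7	21	50.70	8.75	21
Alcohol units per week	15.81	9.39	21	18.61	21.32	21
Diet score	95.24	48.55	21	40.66	32.92	21
GHQ 28 score	1.48	2.71	21	5.00	5.59	21
NART errors	5.33	3.719	21	12.43	6.66	21
Choice reaction time	860.14	115.66	21	1064.48	168.6	21
Trail making test A	28.55	7.59	21	35.86	12.97	21
Trail making test B	61.74	20.81	21	90.42	29.98	21
RAVLT trial 5	12.05	1.74	21	11.52	2.06	21
Cortisol (nmol/l)	354.37	103.29	21	398.63	124.06	21
CRP (mg/L)	1.17	1.34	21	3.40	2.94	21
ICAM (ng/ml)	234.48	25.72	21	309.67	84.19	21
IL6 (pg/ml)	2.6235	5.42	21	2.5320	1.76	21
Fibrogen (g/L)	2.94	0.61	21	3.17	0.95	21
D-dimer	89.81	47.35	21	150.32	104.27	21
Glucose (mmol/L)	5.42	0.57	21	5.31	1.15	21
HDL (mmol/l)	1.22	0.20	21	1.26	0.36	21
Triglycerides (mmol/l)	1.71	0.72	21	2.29	2.23	21
Insulin (uIU/ml)	7.1820	4.82	21	9.857	8.43	21
Systolic BP (mmHg)	139.90	17.03	21	142.47	20.96	21
Diastolic BP (mmHg)	81.28	8.53	21	82.85	11.33	21
BMI (kg/m^2)	27.02	2.69	21	28.42	5.86	21
Waist-Hip ratio	0.90	0.05	21	0.97	0.072	21
Intracranial volume (cc)	1572.94	143.52	21	1542.66	161.72	21
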