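panel	trait	group	mean	sd	n	letter
carcass_meat	Live Weight at Slaughter (kg)	high	148.38	8.97	4	A
carcass_meat	Live Weight at Slaughter (kg)	low	88.75	9.13	4	B
carcass_meat	Percentage of Skin Fat (%)	high	40.74	6.02	4	
carcass_meat	Percentage of Skin Fat (%)	low	40.73	2.80	4	
carcass_meat	Percentage of Lean Meat (%)	high	44.05	3.30	4	
carcass_meat	Percentage of Lean Meat (%)	low	43.17	2.81	4	
carcass_meat	Dressing Percentage (%)	high	76.76	1.09	4	
carcass_meat	Dressing Percentage (%)	low	78.08	3.46	4	
carcass_meat	Loin Eye Area (cm2)	high	36.13	6.07	4	a
carcass_meat	Loin Eye Area (cm2)	low	25.72	4.90	4	b
carcass_meat	Backfat Thickness Middle Shoulder (mm)	high	57.83	12.87	4	
carcass_meat	Backfat Thickness Middle Shoulder (mm)	low	58.83	8.73	4	
carcass_meat	Backfat Thickness Thoracolumbar Junction (mm)	high	29.27	8.12	4	b
carcass_meat	Backfat Thickness Thoracolumbar Junction (mm)	low	35.58	4.54	4	a
carcass_meat	Backfat Thickness Lumbar Sacral Vertebra Junction (mm)	high	31.47	11.07	4	
carcass_meat	Backfat Thickness Lumbar Sacral Vertebra Junction (mm)	low	32.32	2.57	4	
carcass_meat	pH 45 min	high	6.51	0.10	4	
carcass_meat	pH 45 min	low	6.40	0.24	4	
carcass_meat	pH 24 h	high	5.69	0.04	4	a
carcass_meat	pH 24 h	low	5.60	0.14	4	b
carcass_meat	Meat Color 45 min	high	85.43	2.45	4	
carcass_meat	Meat Color 45 min	low	84.85	2.55	4	
carcass_meat	Meat Color 24 h	high	65.58	5.30	4	
carcass_meat	Meat Color 24 h	low	63.03	6.38	4	
carcass_meat	Colorimetric Meat Color Score 45 min	high	3.50	0.58	4	
carcass_meat	Colorimetric Meat Color Score 45 min	low	3.00	0.00	4	
carcass_meat	Colorimetric Meat Color Score 24 h	high	2.00	0.00	4	
carcass_meat	Colorimetric Meat Color Score 24 h	low	2.00	0.00	4	
carcass_meat	Drip Loss 48 h (g)	high	0.54	0.17	4	
carcass_meat	Drip Loss 48 h (g)	low	0.48	0.19	4	
carcass_meat	Share Force (KGF)	high	7.82	0.82	4	
carcass_meat	Share Force (KGF)	low	7.95	1.52	4	
carcass_meat	Moisture (%)	high	74.17	0.01	4	
carcass_meat	Moisture (%)	low	73.49	0.01	4	
carcass_meat	IMF (%)	high	2.60	0.008	4	b
carcass_meat	IMF (%)	low	3.99	0.015	4	a
serum	Total Protein (mg/mL)	high	31.20	3.00	4	b
serum	Total Protein (mg/mL)	low	36.23	0.40	4	a
serum	Cholesterol (mmol/mL)	high	4.03	0.47	4	b
serum	Cholesterol (mmol/mL)	low	5.67	0.92	4	a
serum	Triglycerides (mmol/mL)	high	0.86	0.38	4	
serum	Triglycerides (mmol/mL)	low	1.21	0.19	4	
serum	Creatinine (umol/mL)	high	630.39	69.83	4	
serum	Creatinine (umol/mL)	low	534.91	72.98	4	
serum	Glucose (mg/mL)	high	1.82	0.17	4	
serum	Glucose (mg/mL)	low	1.74	0.33	4	
serum	Urea Nitrogen (mmol/mL)	high	5.03	1.60	4	
serum	Urea Nitrogen (mmol/mL)	low	7.40	0.55	4	
fiber_diameter	Muscle Fiber Diameter (um)	high	40.87	3.85	4	
fiber_diameter	Muscle Fiber Diameter (um)	low	40.34	5.68	4	
fiber_type	Type I Muscle Fibers (%)	high	14.1	1.61	4	b
fiber_type	Type I Muscle Fibers (%)	low	19.9	1.18	4	a
fiber_type	Type II Muscle Fibers (%)	high	85.9	4.77	4	a
fiber_type	Type II Muscle Fibers (%)	low	80.1	5.30	4	b
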