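category	AD	ALS	FTD	integrative
Immune/Inflammatory/Infectious	2	1	2	1
Metabolic	1	2	3	2
Cardiovascular	3	9	4	3
Gastrointestinal	4	8	5	4
Endocrine	5	6	6	5
Hematological	6	7	7	6
Other/Neuro-Psych	7	13	1	7
Kidney	8	12	9	11
Liver	9	4	10	8
Dermatological	10	11	12	13
Sensory (EET)	11	3	13	9
Environmental Toxins	12	5	11	10
Musculoskeletal/Orthopedic	13	10	8	12
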