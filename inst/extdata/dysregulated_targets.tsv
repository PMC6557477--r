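gene	pattern	tissue	spermatogonia	spermatocytes	spermatids	trend_label	hormone_annotation	hormone_class
Serpina1b	generational	Spermatozoa	3.89	4.44	4.53	yes	Glucocorticoid	glucocorticoid
Serpina1e	generational	Spermatozoa	NA	NA	NA	NA	Glucocorticoid	glucocorticoid
Serpina3k	generational	Spermatozoa	3.28	3.43	3.55	yes	Glucocorticoid	glucocorticoid
Serpinc1	generational	Spermatozoa	4.17	4.19	4.43	yes	Glucocorticoid	glucocorticoid
Spink1	DEHP-susceptibility	Spermatozoa	3.37	3.43	3.64	yes	Androgen	androgen
Sva	DEHP-susceptibility	Seminal vesicle	3.39	3.54	3.73	yes	Androgen	androgen
Svs2	DEHP-susceptibility	Seminal vesicle	3.13	3.21	3.36	yes	Androgen	androgen
Svs3a	DEHP-susceptibility	Spermatozoa	4.12	4.57	4.53	no	Androgen	androgen
Svs3b	DEHP-susceptibility	Spermatozoa	NA	NA	NA	NA	Androgen	androgen
Svs4	DEHP-susceptibility	Spermatozoa	3.26	3.56	4.39	yes	Androgen	androgen
Svs5	DEHP-susceptibility	Seminal vesicle	5.30	5.26	5.35	no	Androgen	androgen
Svs6	DEHP-susceptibility	Seminal vesicle	3.16	3.23	3.30	yes	Androgen	androgen
Pate4	DEHP-susceptibility	Spermatozoa	3.00	3.31	3.60	yes	Androgen	androgen
Lcn5	DEHP-resistance	Epididymis-specific	4.46	4.96	5.02	yes	Androgen	androgen
Lcn8	DEHP-resistance	Epididymis-specific	4.84	5.359	5.364	yes	Androgen	androgen
Lcn9	DEHP-resistance	Epididymis-specific	3.75	4.20	4.75	yes	Androgen	androgen
Mup3	generational	Urine	3.34	3.44	3.55	yes	Androgen	androgen
Defb30	DEHP-resistance	Epididymis-specific	NA	NA	NA	NA	Androgen	androgen
Spag11b	DEHP-resistance	Epididymis-specific	NA	NA	NA	NA	Androgen	androgen
Ces1c	generational	Male reproductive tract	3.47	3.82	3.95	yes	Glucocorticoid	glucocorticoid
Ces3a	generational	Male reproductive tract	NA	NA	NA	NA	Androgen	androgen
F2	generational	Serum & sperm	5.29	5.62	5.83	yes	?	none
Fgb	generational	Serum & sperm	4.07	4.31	5.05	yes	Glucocorticoid	glucocorticoid
Plg	generational	Serum & sperm	3.84	4.08	4.05	no	Androgen regulator	androgen
Gpx5	DEHP-resistance	Epididymis-specific	3.56	4.13	4.47	yes	Androgen	androgen
Pon1	generational	Serum & sperm	4.16	4.47	4.82	yes	Androgen	androgen
Spint4	DEHP-resistance	Epididymis-specific	3.43	3.58	3.66	yes	Androgen	androgen
9230104L09Rik	DEHP-resistance	Spermatozoa	5.30	6.03	6.16	yes	Androgen	androgen
Wfdc21	generational	Epididymis-specific	4.72	4.85	5.02	yes	Estrogen	estrogen
Apoa1	generational	High density lipoprotein & sperm	4.92	5.10	5.32	yes	T3-Thyroid hormone	t3
Apoa2	generational	High density lipoprotein	5.48	6.18	6.41	yes	T3-Thyroid hormone	t3
Apoc3	generational	Very-low-density lipoproteins	3.76	3.98	4.07	yes	H-response enhancer	none
Apoh	generational	Liver	4.15	5.81	7.15	yes	regulated by cis-acting elements	none
Apom	generational	High density lipoprotein	5.15	5.67	5.73	yes	estrogen	estrogen
Cml2	generational	Brain and testis	3.64	3.99	3.85	no	PPAR	ppar
Gc	generational	Serum & sperm	3.38	3.65	3.73	yes	-	none
Orm1	generational	Serum & sperm	3.05	3.18	3.30	yes	Glucocorticoid	glucocorticoid
Cyp2d9	generational	Liver	3.66	4.03	4.28	yes	Androgen	androgen
Cyp3a11	generational	Liver	3.22	3.29	3.23	no	Testosterone hydroxylation	androgen
Fabp1	generational	Liver, serum	3.29	3.63	4.23	yes	PPAR	ppar
Aldob	generational	Liver	4.67	5.07	5.77	yes	Glucocorticoid	glucocorticoid
mir192	generational	Sperm and adipocytes	NA	NA	NA	NA	Glucocorticoid	glucocorticoid
Saa2	DEHP-susceptibility	Serum & sperm	4.67	4.88	5.07	yes	Androgen	androgen
Alb	generational	Liver	4.23	4.48	4.63	yes	Glucocorticoid	glucocorticoid
Uox	generational	Liver	3.90	4.89	4.91	yes	Glucocorticoid	glucocorticoid
Azgp1	generational	Adipocyte, prostate	4.97	5.41	5.87	yes	Glucocorticoid	glucocorticoid
Cps1	generational	Testis	4.10	4.30	4.56	yes	Glucocorticoid	glucocorticoid
Slco1b2	generational	Liver	3.27	3.41	3.57	yes	PPAR	ppar
Sult2a8	generational	Liver	NA	NA	NA	NA	PPAR	ppar
Akr1c6	generational	Liver	3.39	3.66	3.65	no	regulator of sex hormones	none
Ahsg	generational	Serum, bones	5.39	5.14	5.75	no	regulator of lipids hormones	none
Rdh7	generational	Testis	3.58	3.73	3.79	yes	regulator of androgens activity	androgen
Hpd	generational	Liver	4.02	3.87	3.91	no	Hormone	none
Bhmt	generational	Liver	4.53	5.48	4.44	no	taurine-regulated	none
Hamp	generational	Hepatocyte and blood	3.61	3.81	4.04	yes	peptide hormone	none
C9	generational	Serum & sperm	4.21	4.70	5.27	yes	immuno-regulation	none
Slc38a3	generational	Brain, Liver, Placenta	5.87	6.17	6.54	yes	Glucocorticoid	glucocorticoid
9530003J23Rik	DEHP-susceptibility	Spermatozoa	3.34	3.23	3.34	no	-	none
Haao	generational	Brain	4.98	5.59	5.74	yes	-	none
Ttc36	generational	Testis	4.67	5.40	5.77	yes	-	none
Hpx	generational	Liver	4.27	4.46	4.41	no	-	none
Rprl3	DEHP-resistance	All cells	NA	NA	NA	NA	-	none
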