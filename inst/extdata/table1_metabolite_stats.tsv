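metabolite	fold_change	direction	q_value	vip	flag_oplsda	flag_biosigner	flag_lasso	supplementary
Nicotinamide	0.643	down	0.00269	2.06794	TRUE	TRUE	TRUE	FALSE
Arginine	1.312	up	0.00375	1.36764	TRUE	FALSE	TRUE	FALSE
Glyceraldehyde	1.106	up	0.00375	0.94874	FALSE	FALSE	FALSE	FALSE
N-acetyl-L-leucine	1.846	up	0.00375	2.02646	TRUE	TRUE	FALSE	FALSE
Galactose	1.103	up	0.00444	0.93104	FALSE	FALSE	FALSE	FALSE
Hypoxanthine	0.558	down	0.00444	3.13134	TRUE	FALSE	FALSE	FALSE
1-methyl-6,7-dihydroxy-1,2,3,4-tetrahydroisoquinoline	0.469	down	0.00444	2.61827	TRUE	FALSE	FALSE	FALSE
Glyoxylic acid	1.097	up	0.00523	0.90817	FALSE	FALSE	FALSE	FALSE
Arabinose	1.121	up	0.00523	0.98914	FALSE	FALSE	FALSE	FALSE
Xanthine	0.727	down	0.00629	1.95504	TRUE	FALSE	FALSE	FALSE
3-hydroxybenzaldehyde	1.325	up	0.00938	1.12595	FALSE	FALSE	FALSE	FALSE
Tyrosine	1.213	up	0.01127	1.30588	FALSE	FALSE	FALSE	FALSE
Indole-3-acetate	1.449	up	0.01791	1.36766	FALSE	FALSE	FALSE	FALSE
Urocanate	0.733	down	0.01791	1.58454	FALSE	FALSE	FALSE	FALSE
Uracil	1.048	up	0.02246	0.42581	FALSE	FALSE	FALSE	FALSE
N-acetylputrescine	0.812	down	0.02285	1.24824	FALSE	FALSE	FALSE	FALSE
3-hydroxyphenylacetate	1.398	up	0.02285	1.37148	FALSE	FALSE	FALSE	FALSE
Glycolate	1.13	up	0.02285	0.84268	FALSE	FALSE	FALSE	FALSE
Rac-glycerol 1-myristate	1.316	up	0.03136	1.63356	TRUE	FALSE	FALSE	FALSE
Methionine	1.163	up	0.03268	1.27457	FALSE	FALSE	FALSE	FALSE
Alpha-aminoadipate	1.306	up	0.03409	1.59113	FALSE	FALSE	FALSE	FALSE
Cystathionine	1.656	up	0.03886	2.46291	FALSE	FALSE	FALSE	FALSE
Cortisone	1.35	up	0.04246	0.88469	FALSE	FALSE	FALSE	FALSE
Uridine	0.811	down	0.04246	1.41792	FALSE	FALSE	FALSE	FALSE
cis-4-hydroxy-d-proline	1.443	up	0.04444	1.32333	FALSE	FALSE	FALSE	FALSE
4-hydroxy-l-proline	1.432	up	0.04463	1.32638	FALSE	FALSE	FALSE	FALSE
Cystine	0.841	down	0.04487	1.0005	FALSE	FALSE	FALSE	FALSE
1-oleoyl-rac-glycerol	1.608	up	0.04906	1.53561	TRUE	FALSE	FALSE	FALSE
5,6-dihydrouracil	NA	NA	0.0986	NA	FALSE	FALSE	FALSE	TRUE
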