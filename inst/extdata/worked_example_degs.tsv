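# Worked-example DEG table: domestic-versus-wild contrasts transcribed from the
# published narrative. log2fc is expression in the domestic (or tame) animal
# relative to its wild (or aggressive) congener. Magnitudes printed in the source
# are used verbatim; the rest are synthetic placeholders (see note column) —
# only the sign enters the analysis. pvalue is the source study's significance
# call where available, NA otherwise.
symbol	domestic_taxon	wild_taxon	tissue	log2fc	pvalue	source	note
Apoa1	Cavia porcellus	Cavia aperea	frontal cortex	-3.2	0.01	Albert et al. 2012	
Cetp	Cavia porcellus	Cavia aperea	frontal cortex	1.7	0.01	Albert et al. 2012	magnitude synthetic; domestic excess per narrative
Cyp17a1	Cavia porcellus	Cavia aperea	frontal cortex	-1.1	0.01	Albert et al. 2012	magnitude synthetic; domestic deficiency per narrative
Cyp17a1	Gallus gallus domesticus	Gallus gallus	hypothalamus	0.9	0.01	Fallahshahroudi et al. 2019	magnitude synthetic; wild deficiency per narrative
Gcg	Cavia porcellus	Cavia aperea	frontal cortex	1.4	0.01	Albert et al. 2012	magnitude synthetic; domestic excess per narrative
Il1b	Cavia porcellus	Cavia aperea	frontal cortex	0.8	0.01	Albert et al. 2012	sign ambiguous in narrative (both directions attached to the wild lineage); transcribed as domestic-up to satisfy the printed marginals
Nr5a1	Cavia porcellus	Cavia aperea	frontal cortex	-0.6	0.01	Albert et al. 2012	sign ambiguous in narrative (both directions attached to the domestic lineage); transcribed as domestic-down to satisfy the printed marginals
Proc	Cavia porcellus	Cavia aperea	frontal cortex	1.2	0.01	Albert et al. 2012	magnitude synthetic; wild deficiency per narrative
F7	Oryctolagus cuniculus domesticus	Oryctolagus cuniculus	frontal cortex	-1.0	0.01	Albert et al. 2012	magnitude synthetic; domestic deficiency per narrative
F3	Gallus gallus domesticus	Gallus gallus	hypothalamus	1.3	0.01	Fallahshahroudi et al. 2019	magnitude synthetic; domestic excess per narrative
Gh1	Canis familiaris	Canis lupus	blood	2.1	0.01	Yang X. et al. 2018	magnitude synthetic; domestic excess per narrative
Hba1	Canis familiaris	Canis lupus	blood	-1.8	0.01	Yang X. et al. 2018	magnitude synthetic; domestic hemoglobin underexpression per narrative
Hbbl	Canis familiaris	Canis lupus	blood	-2.4	0.01	Yang X. et al. 2018	magnitude synthetic; domestic hemoglobin underexpression per narrative
Hbad	Gallus gallus domesticus	Gallus gallus	hypothalamus	-1.2	0.01	Fallahshahroudi et al. 2019	magnitude synthetic; domestic hemoglobin underexpression per narrative
Hbm	Gallus gallus domesticus	Gallus gallus	hypothalamus	-0.9	0.01	Fallahshahroudi et al. 2019	magnitude synthetic; domestic hemoglobin underexpression per narrative
Hbz1	Gallus gallus domesticus	Gallus gallus	hypothalamus	-1.5	0.01	Fallahshahroudi et al. 2019	magnitude synthetic; domestic hemoglobin underexpression per narrative
Esr2	Vulpes vulpes (tame)	Vulpes vulpes (aggressive)	pituitary gland	0.5	0.01	Hekman et al. 2018	sign immaterial (both human directions potential-decreasing); magnitude synthetic
Il9r	Vulpes vulpes (tame)	Vulpes vulpes (aggressive)	pituitary gland	0.7	0.01	Hekman et al. 2018	magnitude synthetic; tame-lineage excess per narrative
Pgr	Gallus gallus domesticus	Gallus gallus	hypothalamus	1.6	0.01	Fallahshahroudi et al. 2019	magnitude synthetic; domestic excess per narrative
Slc25a6	Gallus gallus domesticus	Gallus gallus	hypothalamus	1.1	0.01	Fallahshahroudi et al. 2019	magnitude synthetic; domestic excess per narrative
Ckbl	Canis familiaris	Canis lupus	blood	4.33	0.01	Yang X. et al. 2018	no annotated human ortholog; excluded at matching
Adm	Canis familiaris	Canis lupus	frontal cortex	-1.55	0.01	Albert et al. 2012	no annotated human ortholog
Hpd	Vulpes vulpes (tame)	Vulpes vulpes (aggressive)	pituitary gland	-0.47	0.01	Hekman et al. 2018	no annotated human ortholog
Mdk	Sus scrofa domesticus	Sus scrofa	frontal cortex	0.85	0.01	Albert et al. 2012	magnitude synthetic; domestic excess per narrative; no annotated human ortholog
C7	Sus scrofa domesticus	Sus scrofa	frontal cortex	1.21	0.01	Long et al. 2018	magnitude synthetic; domestic excess per narrative; no annotated human ortholog
Ano3	Sus scrofa domesticus	Sus scrofa	pituitary gland	-1.32	0.01	Yang Y. et al. 2018	no annotated human ortholog
Agt	Cavia porcellus	Cavia aperea	frontal cortex	-0.92	0.01	Albert et al. 2012	magnitude synthetic; domestic deficiency per narrative; no annotated human ortholog
Gp2	Sus scrofa domesticus	Sus scrofa	pituitary gland	0.66	0.05	Yang Y. et al. 2018	sign and magnitude synthetic; no annotated human ortholog
ApoD	Cavia porcellus	Cavia aperea	frontal cortex	-0.58	0.05	Albert et al. 2012	sign and magnitude synthetic; no annotated human ortholog
Pgk1	Gallus gallus domesticus	Gallus gallus	hypothalamus	0.44	0.05	Fallahshahroudi et al. 2019	sign and magnitude synthetic; no annotated human ortholog
Aqp1	Canis familiaris	Canis lupus	blood	-0.73	0.05	Yang X. et al. 2018	sign and magnitude synthetic; no annotated human ortholog
Irf6	Sus scrofa domesticus	Sus scrofa	frontal cortex	0.52	0.05	Albert et al. 2012	sign and magnitude synthetic; no annotated human ortholog
Alb	Vulpes vulpes (tame)	Vulpes vulpes (aggressive)	pituitary gland	-0.61	0.05	Hekman et al. 2018	sign and magnitude synthetic; no annotated human ortholog
Fst	Gallus gallus domesticus	Gallus gallus	hypothalamus	0.77	0.05	Fallahshahroudi et al. 2019	sign and magnitude synthetic; no annotated human ortholog
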