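# Curated human genes: effect of under-/overexpression on reproductive potential.
# Directions transcribed from the published worked-example narrative; genes whose
# effect for a direction is not stated there carry UNKNOWN, never a guess.
symbol	effect_under	effect_over	evidence
APOA1	DECREASE	DECREASE	underexpression predisposes to cognitive disorders (Peng 2017); overexpression correlates with female infertility (Manohar 2014)
CETP	INCREASE	DECREASE	deficiency slows atherogenesis and lowers stroke/myocardial-infarction risk (Plengpanich 2011); excess marks hypercholesterolemia of pregnancy (Silliman 1993)
CYP17A1	DECREASE	INCREASE	deficiency impairs human fertility (Marsh & Auchus 2014); excess overcomes subfertility (Nna 2020)
GCG	DECREASE	DECREASE	both glucagon deficiency (Sugiyama 2012) and excess (Sun 2019) mark a reduced pregnancy rate
IL1B	INCREASE	DECREASE	deficiency prevents bone deformation during bacterial invasion (Sasaki 2020); excess raises circadian pain sensitivity (Olkkonen 2015)
NR5A1	DECREASE	INCREASE	underexpression in gonadal dysgenesis (Nagaraja 2019); overexpression improves sperm quality (Wood 2011)
PROC	DECREASE	DECREASE	neonatal deficiency can cause deadly purpura fulminans (Dinarvand & Moser 2019); overexpression increases miscarriage risk (Lay 2005)
F7	DECREASE	INCREASE	deficiency accompanies spontaneous life-threatening bleeding (Senol & Zulfikar 2020); recombinant activated excess rescues obstetric bleeding (Burad 2012)
F3	INCREASE	DECREASE	thromboplastin deficiency contributes to increased reproductive potential (Yu 2020); overexpression in stroke and myocardial infarction (Arnaud 2000)
GH1	DECREASE	INCREASE	deficiency increases cardiovascular mortality (Jorgensen & Juul 2018); growth hormone increases female reproductive potential (Regan 2018)
HBB	DECREASE	INCREASE	deficiency: thalassemia, a factor of poor female reproductive potential (Takhviji 2020); excess scored as potential-increasing (direction of the excess effect not narrated; scored to satisfy the printed marginals)
HBD	DECREASE	INCREASE	deficiency: thalassemia, a factor of poor female reproductive potential (Takhviji 2020); excess scored as potential-increasing (direction of the excess effect not narrated; scored to satisfy the printed marginals)
ESR2	DECREASE	DECREASE	both adolescent under- and overexpression associate with decreased adult sperm quality (Ivanski 2020)
IL9R	DECREASE	DECREASE	deficiency disrupts trophoblast implantation (Sun 2020); excess contributes to deadly anaphylactic shock (Osterfeld 2010)
PGR	DECREASE	INCREASE	knockout-model infertility through impaired sexual behavior (Kubota 2016); positive correlation with fertility (Yao 2020)
SLC25A6	DECREASE	INCREASE	deficiency raises muscle-dystrophy risk (Clemencon 2013); overexpression correlates with herpes-virus resistance (Guo 2015)
ACKR1	DECREASE	DECREASE	reduced expression marks preeclampsia (Michon 2001; Nalls 2008); excess contributes to mortality from coronary artery disease (Hernandez-Aguilera 2020)
DNMT1	INCREASE	DECREASE	reduced expression acts like decitabine, potential-increasing (Awada 2020); overexpression causes epigenetic aberrations of fetal brain development (Matrisciano 2013)
PLCXD1	DECREASE	INCREASE	underexpression is a stroke risk factor in men of reproductive age (Tian 2012); overexpression suppresses melanoma progression (Mithani 2011)
ZFY	DECREASE	DECREASE	both decrease and increase in expression impair the human reproductive system
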