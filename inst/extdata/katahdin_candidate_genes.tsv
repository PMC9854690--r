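# fecundscan example data: published candidate-gene set for fecundity in Katahdin ewes (Ovis aries, OvineSNP50 scan; FST and ROH selection signatures)
gene	method	group	chrom	position	function_summary
CNOT11	FST	high	3	100058810	Pregnancy rate
ATG10	FST	high	5	79156925	Autophagy and innate immune defense
RPS23	FST	high	5	79446021	Protein synthesis and immunity
ANK2	FST	high	6	12314476	Structure of ovarian granulosa cells
CAMK2D	FST	high	6	11870774	Fat metabolism and meat quality traits
STK32B	FST	high	6	103213333	Fat deposition and marbling
UGT8	FST	high	6	11004274	Development and function of the nervous and endocrine systems
ADIRF	ROH	high	25	41056054	Adipose deposition tissue
ARHGAP22	ROH	high	25	42255625	Fertility traits, lipid metabolism, insulin resistance, and inflammation response
GHITM	ROH	high	25	38626280	Metritis and fertility traits
GLUD1	ROH	high	25	41085197	Follicular development and maturation
GRID1	ROH	high	25	39879600	Litter size
LRIT1	ROH	high	25	38706733	Cellular energy
MAPK8	ROH	high	25	42210625	Follicular development
MMRN2	ROH	high	25	41018603	Cell differentiation or organogenesis
TRNAC-GCA	ROH	high	25	39208014	Plasma urea concentration and sperm quality
VSTM4	ROH	high	25	42748968	Cumulus cells and somatic cell nuclear transfer
HERC6	ROH	low	6	36181502	Pregnancy rate
CCL28	ROH	low	16	31346400	Lymphocyte colonization of fetal tissues
GHR	ROH	low	16	31832298	Growth performance, carcass traits, milk traits, and cell differentiation
HMGCS1	ROH	low	16	31409821	Cholesterol biosynthesis
DPF2	ROH	low	21	42741418	Fertility
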