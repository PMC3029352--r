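family	regulated_process	induced_genes	n_classes
basic helix-loop-helix (bHLH)	transcription	13	6
bZIP	transcription	7	4
CCAAT-binding TF	transcription	5	4
CCR4-NOT	transcription	3	3
DNA-binding protein-like	transcription	3	3
ERF/AP2	transcription	24	7
G2-like	transcription	1	1
GRAS	transcription	6	3
HB	transcription	9	5
HSF	transcription	2	2
KH	post-transcriptional	1	1
LIM domain-containing protein	transcription	1	1
LOB domain protein	transcription	1	1
MADS box	transcription	1	1
TFIIS	transcription	1	1
Myb	transcription	18	9
no apical meristem (NAM)	transcription	12	6
ovate protein family	transcription	1	1
RWP-RK domain protein	transcription	1	1
S1FA	transcription	1	1
SAR DNA-binding protein	transcription	1	1
TFIIS containing protein	transcription	1	1
WRKY	transcription	24	1
Zinc finger (Ran-binding)	nuclear protein import	1	1
Zinc finger, AN1-like	protein degradation	4	4
Zinc finger, B-box type	transcription	3	2
Zinc finger, C2H2 type	transcription	10	5
Zinc finger, CCCH-type	post-transcriptional reg.	7	6
Zinc finger, CCHC-type	unclear	1	1
Zinc finger, DHHC type	unclear	1	1
Zinc finger, Dof-type	transcription	1	1
Zinc finger, FYVE/PHD-type	unclear	1	1
Zinc finger, GRF-type	unclear	1	1
Zinc finger, RING-type	protein degradation	23	6
Zinc finger, TAZ-type	chromatin remodeling	2	2
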