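network	network_label	component	region	abbreviation	x	y	z
Default mode network	DMN	18	Posterior cingulate gyrus	PCC	3	-52	26
Default mode network	DMN	18	Medial prefrontal cortex	MPFC	3	58	6
Left executive network	LEXE	2	Left superior frontal gyrus	LSFG	-33	22	52
Left executive network	LEXE	2	Left superior parietal lobule	LSPL	-50	-51	50
Right executive network	REXE	17	Right superior frontal gyrus	RSFG	27	28	52
Right executive network	REXE	17	Right superior parietal lobule	RSPL	36	-66	48
Salience network	SAL	14	Left inferior frontal gyrus	LIFG	-48	19	-5
Salience network	SAL	14	Right inferior frontal gyrus	RIFG	48	16	-5
Dorsal attention network	ATT	20	Left inferior parietal lobule	LIPL	-45	-42	56
Dorsal attention network	ATT	20	Right inferior parietal lobule	RIPL	48	-39	55
Auditory network	AUD	4	Left superior temporal gyrus	LSTG	-62	-1	9
Auditory network	AUD	4	Right superior temporal gyrus	RSTG	62	-26	16
Extrastriate network	EXT	9	Left middle temporal gyrus	LMTG	-50	-65	10
Extrastriate network	EXT	9	Right superior temporal gyrus	RMTG	45	-76	10
Motor network	MOT	13	Left precentral gyrus	LPCG	-48	-7	54
Motor network	MOT	13	Right precentral gyrus	RPCG	45	-13	54
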