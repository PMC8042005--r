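gene_id	symbol	family	stress_induced	diseases	disease_tissues	orthologs_celegans	orthologs_mouse
ENSG00000106211	HSPB1	sHSP	TRUE	Charcot-Marie-Tooth disease 2F	nerve;muscle	hsp-16.1	Hspb1
ENSG00000160789	HSPB7	sHSP	FALSE			Hspb7	Hspb7
ENSG00000204389	HSPA1A	HSP70	TRUE			hsp-70	Hspa1a
ENSG00000109971	HSPA8	HSP70	FALSE		 	hsp-1	Hspa8
ENSG00000044574	HSPA5	HSP70	FALSE	autosomal	liver	hsp-3;hsp-4	Hspa5
ENSG00000080824	HSP90AA1	HSP90	TRUE			hsp-90	Hsp90aa1
ENSG00000096384	HSP90AB1	HSP90	FALSE			hsp-90	Hsp90ab1
ENSG00000166598	HSP90B1	HSP90	FALSE			enpl-1	Hsp90b1
ENSG00000144381	HSPD1	HSP60/HSP10	FALSE	hereditary spastic paraplegia 13	nerve	hsp-60	Hspd1
ENSG00000115541	HSPE1	HSP60/HSP10	FALSE			hsp-6	Hspe1
ENSG00000213719	DNAJB1	HSP40	TRUE			dnj-13	Dnajb1
ENSG00000105993	DNAJB6	HSP40	FALSE	limb-girdle muscular dystrophy 1E	muscle	dnj-24	Dnajb6
ENSG00000103423	DNAJA3	HSP40	FALSE			dnj-10	Dnaja3
ENSG00000151929	BAG3	NEF	TRUE	myofibrillar myopathy 6	muscle;heart		Bag3
ENSG00000114120	SIL1	NEF	FALSE	Marinesco-Sjogren syndrome	brain;muscle;eye	sil-1	Sil1
ENSG00000166226	CCT2	other	FALSE			cct-2	Cct2
ENSG00000150753	CCT5	other	FALSE	hereditary sensory neuropathy	nerve	cct-5	Cct5
ENSG00000155100	PFDN2	prefoldin	FALSE			pfd-2	Pfdn2
ENSG00000110958	PTGES3	coHSP90	FALSE		 		Ptges3
ENSG00000126524	STIP1	coHSP90	FALSE			sti-1	Stip1
ENSG00000102265	FKBP14	folding enzyme	FALSE	Ehlers-Danlos syndrome	skin;muscle		Fkbp14
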