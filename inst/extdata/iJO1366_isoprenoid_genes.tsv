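locus_tag	gene	enzyme
b0420	dxs	1-deoxy-D-xylulose-5-phosphate synthase
b0173	dxr	1-deoxy-D-xylulose reductoisomerase
b2747	ispD	2-C-methyl-D-erythritol 4-phosphate cytidylyltransferase
b1208	ispE	4-(cytidine 5'-diphospho)-2-C-methyl-D-erythritol kinase
b2746	ispF	2-C-methyl-D-erythritol 2,4-cyclodiphosphate synthase
b2515	ispG	2-C-methyl-D-erythritol 2,4-cyclodiphosphate dehydratase
b0029	ispH	1-hydroxy-2-methyl-2-(E)-butenyl 4-diphosphate reductase
b2889	idi	isopentenyl-diphosphate D-isomerase
b0421	ispA	farnesyl diphosphate synthase
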