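gene	gene_id	length_bp	vector	checked	positive	start	end
yaiS	946967	558	pET22b	8	7	NA	NA
ybaY	945070	574	pET22b	8	8	NA	NA
nfnB	945778	654	pET22b	8	6	NA	NA
yohK	949125	696	pET22b	8	8	NA	NA
rlmB	948694	732	pET22b	8	8	NA	NA
nhoA	947251	846	pET22b	8	7	NA	NA
dapA	946952	879	pET22b	8	8	NA	NA
deoC	948902	780	pET22b	8	6	NA	NA
deoA	948901	1230	pET22b	8	5	NA	NA
deoB	948910	1224	pET22b	8	8	NA	NA
deoD	945654	721	pET22b	8	7	NA	NA
yjjJ	944883	1332	pET22b	8	8	NA	NA
lplA	944865	1017	pET22b	8	8	NA	NA
ytjB	946089	645	pET22b	8	7	NA	NA
serB	948913	969	pET22b	8	8	NA	NA
radA	948912	1383	pET22b	8	7	NA	NA
yhdP	2847740	3801	pET22b	8	4	NA	NA
yjjK	948909	1668	pET22b	8	8	NA	NA
slt	948908	1938	pET22b	8	8	NA	NA
yjiQ	948866	561	pET22b	8	6	NA	NA
yjiR	949089	1413	pET22b	8	8	NA	NA
yjiS	948903	165	pET22b	8	8	NA	NA
yjiT	945056	1503	pET22b	8	6	NA	NA
yjiV	2847669	2937	pET22b	8	7	NA	NA
mcrC	948880	1047	pET22b	8	8	NA	NA
mcrB	949122	1380	pET22b	8	6	NA	NA
yjiW	7157066	399	pET22b	8	8	NA	NA
hsdS	948867	1395	pET22b	8	8	NA	NA
hsdM	948872	1590	pET22b	8	8	NA	NA
hsdR	948878	3513	pET22b	8	5	NA	NA
mrr	948898	915	pET22b	8	8	NA	NA
yjiA	948882	957	pET22b	8	8	NA	NA
recB	947286	3543	pET22b	8	5	NA	NA
yjiY	948914	2151	pET22b	8	8	NA	NA
tsr	948884	1656	pET22b	8	8	NA	NA
yjiZ	948879	1362	pET22b	8	7	NA	NA
yjjM	7159433	915	pET22b	8	8	NA	NA
yjjN	7159438	1023	pET22b	8	8	NA	NA
mdoB	7159439	2292	pET22b	8	4	NA	NA
yeeJ	946498	7077	pET22b	8	6	NA	NA
gasT	2520	306	pcDNA3.1	8	8	NA	NA
mcm6	4175	2466	pcDNA3.1	8	6	NA	NA
slc18a2	6571	1545	pcDNA3.1	8	7	NA	NA
GeneCluster1	NA	10000	pET22b	8	5	NA	NA
GeneCluster2	NA	15000	pET22b	8	6	NA	NA
GeneCluster3	NA	20441	pET22b	8	4	200485	220925
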