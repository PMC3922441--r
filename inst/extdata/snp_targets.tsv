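panel	rsid	chrom	pos	ref_allele	alt_allele	hgvs
BCL11A	rs11886868	NC_000002.11	60720246	C	T	NC_000002.11:g.60720246C>T
BCL11A	rs4671393	NC_000002.11	60720951	A	G	NC_000002.11:g.60720951A>G
BCL11A	rs7557939	NC_000002.11	60721347	G	A	NC_000002.11:g.60721347G>A
BCL11A	rs6732518	NC_000002.11	60708597	C	T	NC_000002.11:g.60708597C>T
BCL11A	rs10189857	NC_000002.11	60713235	A	G	NC_000002.11:g.60713235A>G
BCL11A	rs6545816	NC_000002.11	60714861	A	C	NC_000002.11:g.60714861A>C
BCL11A	rs7599488	NC_000002.11	60718347	C	T	NC_000002.11:g.60718347C>T
BCL11A	rs1427407	NC_000002.11	60718043	T	G	NC_000002.11:g.60718043T>G
BCL11A	rs766432	NC_000002.11	60719970	C	A	NC_000002.11:g.60719970C>A
BCL11A	rs10184550	NC_000002.11	60729294	G	A	NC_000002.11:g.60729294G>A
BCL11A	rs7606173	NC_000002.11	60725451	G	C	NC_000002.11:g.60725451G>C
BCL11A	rs6706648	NC_000002.11	60722040	C	T	NC_000002.11:g.60722040C>T
HBS1L-MYB	rs28384513	NC_000006.11	135376209	T	G	NC_000006.11:g.135376209T>G
HBS1L-MYB	rs7776054	NC_000006.11	135418916	A	G	NC_000006.11:g.135418916A>G
HBS1L-MYB	rs9399137	NC_000006.11	135419018	T	C	NC_000006.11:g.135419018T>C
HBS1L-MYB	rs9389268	NC_000006.11	135419631	A	G	NC_000006.11:g.135419631A>G
HBS1L-MYB	rs4895441	NC_000006.11	135426573	A	G	NC_000006.11:g.135426573A>G
HBS1L-MYB	rs6929404	NC_000006.11	135454027	C	A	NC_000006.11:g.135454027C>A
HBS1L-MYB	rs9402686	NC_000006.11	135427817	G	A	NC_000006.11:g.135427817G>A
HBS1L-MYB	rs1320963	NC_000006.11	135443212	A	G	NC_000006.11:g.135443212A>G
HBS1L-MYB	rs6904897	NC_000006.11	135382980	T	G	NC_000006.11:g.135382980T>G
HBS1L-MYB	rs35959442	NC_000006.11	135424179	C	G	NC_000006.11:g.135424179C>G
HBS1L-MYB	rs9376090	NC_000006.11	135411228	T	C	NC_000006.11:g.135411228T>C
HBS1L-MYB	rs4895440	NC_000006.11	135426558	A	T	NC_000006.11:g.135426558A>T
HBS1L-MYB	rs9494142	NC_000006.11	135431640	T	C	NC_000006.11:g.135431640T>C
HBS1L-MYB	rs9402685	NC_000006.11	135419688	T	C	NC_000006.11:g.135419688T>C
HBS1L-MYB	rs11759553	NC_000006.11	135422296	A	T	NC_000006.11:g.135422296A>T
HBS1L-MYB	rs6934903	NC_000006.11	135451564	T	A	NC_000006.11:g.135451564T>A
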