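enzyme	pattern	assayed_rsid
AvaII	GGWCC	rs7606173
AatII	GACGTC	rs6706648
BstXI	CCANNNNNNTGG	rs28384513
RsaI	GTAC	rs11759553
MspI	CCGG	rs9376090
HinfI	GANTC	rs4895440
Hpy188III	TCNNGA	rs4895441
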