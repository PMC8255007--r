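chrom	pos	snp	alleles	freq	variance	p
11	31004983	rs110112100	G/A	0.539	126.161	4.369e-09
11	37136773	rs41579835	G/T	0.863	101.135	6.365e-09
11	31034069	rs136576573	T/G	0.490	117.056	1.180e-08
11	31022855	NA	A/G	0.490	117.346	1.206e-08
11	31037875	rs42634817	G/A	0.490	114.435	1.771e-08
11	31049877	rs135661502	C/T	0.581	112.918	2.680e-08
11	31329763	rs43677285	C/T	0.633	100.127	5.626e-08
11	31330363	rs43677273	G/T	0.633	100.127	5.626e-08
11	31332310	rs43677261	G/A	0.633	100.127	5.626e-08
11	31336575	rs43677231	A/C	0.365	99.800	5.931e-08
11	31337157	rs43676629	A/G	0.365	99.800	5.931e-08
11	31338042	rs136274250	C/T	0.635	99.800	5.931e-08
11	31060572	rs135937618	C/A	0.581	106.172	6.378e-08
11	31044741	rs137648582	A/G	0.431	103.469	7.291e-08
11	31070514	rs133193362	A/C	0.419	105.105	7.383e-08
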