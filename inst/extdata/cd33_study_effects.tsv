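stratum	label	or	ci_low	ci_high
unadjusted	ADNI	0.865	0.627	1.193
unadjusted	GenADA	0.864	0.742	1.006
unadjusted	Murcia	0.938	0.763	1.155
unadjusted	NIA	0.956	0.829	1.103
unadjusted	F.ACE	0.986	0.897	1.084
e2_carriers	ADNI	2.2	0.553	8.76
e2_carriers	GenADA	0.863	0.483	1.544
e2_carriers	Murcia	0.492	0.193	1.252
e2_carriers	NIA	1.356	0.660	2.784
e2_carriers	F.ACE	0.682	0.453	1.027
e4_carriers	ADNI	0.979	0.580	1.654
e4_carriers	GenADA	0.697	0.540	0.899
e4_carriers	Murcia	1.133	0.788	1.629
e4_carriers	NIA	0.873	0.691	1.104
e4_carriers	F.ACE	1.153	0.967	1.376
e3e3	ADNI	0.706	0.419	1.187
e3e3	GenADA	1.085	0.862	1.366
e3e3	Murcia	0.849	0.635	1.135
e3e3	NIA	0.908	0.714	1.154
e3e3	F.ACE	0.928	0.818	1.054
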