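species	ion_label	z	k	treatment	fraction	expected_mz	observed_mz
UDP-GlcNAc	(m-1)/1	1	0	Fos_400	C3-C4 F15	606.0738	606.0814
UDP-GlcNAc	(m+Na+-1)/1	1	1	Fos_400	C3-C4 F15	628.0557	628.0628
UDP-GlcNAc	(m-2)/2	2	0	Fos_400	C3-C4 F15	302.5330	302.5352
UDP-MurNAc-Ala	(m-2)/2	2	0	D-cyclo_100	C3-C4 F19	374.0621	374.0696
UDP-MurNAc-Ala	(m-2)/2	2	0	D-cyclo_100	C3-C4 F20	374.0621	374.0698
UDP-MurNAc-Ala	(m-1)/1	1	0	D-cyclo_100	C3-C4 F19	749.1320	749.1476
UDP-MurNAc-Ala	(m-1)/1	1	0	D-cyclo_100	C3-C4 F20	749.1320	749.1488
UDP-MurNAc-Ala	(m+Na+-1)/1	1	1	D-cyclo_100	C3-C4 F19	771.1139	771.1294
UDP-MurNAc-Ala	(m+Na+-1)/1	1	1	D-cyclo_100	C3-C4 F20	771.1139	771.1281
UDP-MurNAc-Ala	(m+2Na+-1)/1	1	2	D-cyclo_100	C3-C4 F19	793.0959	793.1107
UDP-MurNAc-Ala	(m+2Na+-1)/1	1	2	D-cyclo_100	C3-C4 F20	793.0959	793.1127
UDP-MurNAc-Ala	(m+3Na+-1)/1	1	3	D-cyclo_100	C3-C4 F19	815.0778	815.0909
UDP-MurNAc-Ala	(m+3Na+-1)/1	1	3	D-cyclo_100	C3-C4 F20	815.0778	815.0963
UDP-MurNAc-Ala	(m+Na+-2)/2	2	1	D-cyclo_100	C3-C4 F19	385.0531	385.0607
UDP-MurNAc-Ala	(m+Na+-2)/2	2	1	D-cyclo_100	C3-C4 F20	385.0531	385.0611
UDP-MurNAc-Ala-Glu	(m-2)/2	2	0	D-cyclo_100	C3-C4 F23	438.5833	438.5928
UDP-MurNAc-Ala-Glu	(m-2)/2	2	0	D-cyclo_100	C3-4 F24-25	438.5833	438.5935
UDP-MurNAc-Ala-Glu	(m+Na+-2)/2	2	1	D-cyclo_100	C3-C4 F23	449.5744	449.5839
UDP-MurNAc-Ala-Glu	(m+Na+-2)/2	2	1	D-cyclo_100	C3-4 F24-25	449.5744	449.5858
UDP-MurNAc-Ala-Glu	(m+2Na+-2)/2	2	2	D-cyclo_100	C3-C4 F23	460.5653	460.5750
UDP-MurNAc-Ala-Glu	(m+2Na+-2)/2	2	2	D-cyclo_100	C3-4 F24-25	460.5653	460.5716
UDP-MurNAc-Ala-Glu	(m-2)/2	2	0	Cb_100	C7-C8 F23	438.583	438.5916
UDP-MurNAc-Ala-Glu	(m+Na+-2)/2	2	1	Cb_100	C7-C8 F23	449.5744	449.5829
UDP-MurNAc-Ala-Glu	(m+2Na+-2)/2	2	2	Cb_100	C7-C8 F23	460.5653	460.5743
UDP-MurNAc-Ala-Glu	(m-3)/3	3	0	Cb_100	C7-C8 F23	292.0530	292.0575
UDP-MurNAc-Ala-Glu-DAP	(m-2)/2	2	0	KNOPS	C7-C8 F18-19	524.6258	524.6289
UDP-MurNAc-Ala-Glu-DAP	(m-2)/2	2	0	KNOPS	C7-C8 F20	524.6258	524.6289
UDP-MurNAc-Ala-Glu-DAP	(m+Na+-2)/2	2	1	KNOPS	C7-C8 F20	535.6168	535.6196
UDP-MurNAc-Ala-Glu-DAP	(m+2Na+-2)/2	2	2	KNOPS	C7-C8 F20	546.6077	546.6108
UDP-MurNAc-Ala-Glu-DAP	(m-3)/3	3	0	KNOPS	C7-C8 F20	349.4146	349.4155
UDP-MurNAc-Ala-Glu-DAP	(m-2)/2	2	0	D-cyclo_100	C3-C4 F20	524.6258	524.6377
UDP-MurNAc-Ala-Glu-DAP	(m+Na+-2)/2	2	1	D-cyclo_100	C3-C4 F20	535.6168	535.6290
UDP-MurNAc-Ala-Glu-DAP	(m+2Na+-2)/2	2	2	D-cyclo_100	C3-C4 F20	546.6077	546.6197
UDP-MurNAc-Ala-Glu-DAP	(m+3Na+-2)/2	2	3	D-cyclo_100	C3-C4 F20	557.5987	557.6108
UDP-MurNAc-Ala-Glu-DAP	(m-2)/2	2	0	Cb_100	C7-C8 F19	524.6258	524.6317
UDP-MurNAc-Ala-Glu-DAP	(m-2)/2	2	0	Cb_100	C7-C8 F20	524.6258	524.6324
UDP-MurNAc-Ala-Glu-DAP	(m+Na+-2)/2	2	1	Cb_100	C7-C8 F19	535.6168	535.6230
UDP-MurNAc-Ala-Glu-DAP	(m+Na+-2)/2	2	1	Cb_100	C7-C8 F20	535.6168	535.6234
UDP-MurNAc-Ala-Glu-DAP	(m+2Na+-2)/2	2	2	Cb_100	C7-C8 F19	546.6077	546.6139
UDP-MurNAc-Ala-Glu-DAP	(m+2Na+-2)/2	2	2	Cb_100	C7-C8 F20	546.6077	546.6144
UDP-MurNAc-Ala-Glu-DAP	(m+3Na+-2)/2	2	3	Cb_100	C7-C8 F20	557.5987	557.6004
UDP-MurNAc-Ala-Glu-DAP	(m-3)/3	3	0	Cb_100	C7-C8 F19	349.4146	349.4173
UDP-MurNAc-Ala-Glu-DAP	(m-3)/3	3	0	Cb_100	C7-C8 F20	349.4146	349.4178
UDP-MurNAc-Ala-Glu-DAP-Ala-Ala	(m-2)/2	2	0	KNOPS	C7-C8 F18-19	595.6629	595.6646
UDP-MurNAc-Ala-Glu-DAP-Ala-Ala	(m+Na+-2)/2	2	1	KNOPS	C7-C8 F18-19	606.6539	606.6553
UDP-MurNAc-Ala-Glu-DAP-Ala-Ala	(m-3)/3	3	0	KNOPS	C7-C8 F18-19	396.7726	396.7740
UDP-MurNAc-Ala-Glu-DAP-Ala-Ala	(m-2)/2	2	0	Cb_100	C7-C8 F19	595.6629	595.6693
UDP-MurNAc-Ala-Glu-DAP-Ala-Ala	(m+Na+-2)/2	2	1	Cb_100	C7-C8 F19	606.6539	606.6602
UDP-MurNAc-Ala-Glu-DAP-Ala-Ala	(m+2Na+-2)/2	2	2	Cb_100	C7-C8 F19	617.6446	617.6509
UDP-MurNAc-Ala-Glu-DAP-Ala-Ala	(m-3)/3	3	0	Cb_100	C7-C8 F19	396.7726	396.7763
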