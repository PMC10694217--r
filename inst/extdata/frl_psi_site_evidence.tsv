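# Extant structural evidence per chlorophyll site in the three deposited
# FRL-PSI cryo-EM structures: Y = the FRL-specific feature (chlorophyll-f
# occupancy, or the A0B cofactor rotation) is observed in that structure.
structure	A0B_rotation	B7	B37	B38	B30	A21	A23	B19
7LX0_F_thermalis	Y	Y	Y	Y	Y	Y	N	N
7S3D_Synechococcus_7335	Y	Y	Y	Y	Y	Y	N	Y
6KMX_H_hongdechloris	Y	Y	Y	Y	Y	Y	Y	N
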