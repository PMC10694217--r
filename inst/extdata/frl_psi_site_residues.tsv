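# Supporting residues of the candidate chlorophyll-f sites and of the A0B
# rotation in FRL photosystem I, in Fischerella thermalis PCC 7521 author
# numbering (structure 7LX0). `residue` is the author residue number in the
# named FRL-specific subunit; map to alignment columns with
# map_alignment_to_chain() + column_map() before calling
# assign_ancestral_sites(). Roles: hbond_donor = donates the H-bond that
# marks the site; cavity = creates/removes the binding-cavity volume;
# stabilizer = nearby group-specific residue stabilizing the interaction.
site	subunit	residue	role
B7	PsaI2	27	hbond_donor
B7	PsaL2	93	hbond_donor
B37	PsaB2	697	hbond_donor
B37	PsaB2	456	hbond_donor
B37	PsaB2	452	cavity
B38	PsaB2	22	cavity
B30	PsaF2	49	hbond_donor
B30	PsaB2	447	stabilizer
B30	PsaJ2	31	stabilizer
B30	PsaJ2	40	hbond_donor
A0B_rotation	PsaB2	666	cavity
A0B_rotation	PsaB2	667	hbond_donor
A0B_rotation	PsaB2	673	hbond_donor
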