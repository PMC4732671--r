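# Default PROSITE-syntax patterns for the annotation layer.
# The *_syn signatures are synthetic stand-ins matched to the bundled
# synthetic template proteins. For real data, replace them with the curated
# PROSITE entries (PS00719/PS00608 GUS signatures, PS01124 AraC-family HTH).
name	pattern
c7d2_motif	F-G-D-F-[AG]-N-D
c7d2_motif_g	F-G-D-F-G-N-D
c7d2_motif_a	F-G-D-F-A-N-D
gus_sig1_syn	L-[KR]-T-S-H-Y-P-[LIVM]
gus_sig2_syn	G-F-N-[SA]-H-G-[LIVM]-D
aftr_hth_syn	S-[LIVM]-x(2)-[KR]-[LIVM]-F-[KR]-x(2)-G-[ST]
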