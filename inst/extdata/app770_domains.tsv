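# reference=APP770_HUMAN
# Packaged example: approximate conserved-domain boundaries on the human
# amyloid-beta precursor protein 770-residue isoform (1-based inclusive).
# NTS = signal peptide; E1/E2 = ectodomain regions; E3 = C-terminal region
# (transmembrane + cytoplasmic); bA4 = the amyloid-beta-forming region
# (overlaps E3, hence overlapping intervals are expected in this file).
name	start	end
NTS	1	17
E1	28	189
E2	374	565
E3	700	770
bA4	672	713
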