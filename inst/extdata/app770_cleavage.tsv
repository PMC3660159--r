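# Packaged example: secretase cleavage annotation for human APP770
# (1-based inclusive residue coordinates on the APP770 sequence).
# start/end = beta- and gamma-site bounds of the Abeta42 peptide
# (672..713); alpha = first residue of the C-terminal window, i.e. the
# residue following the alpha-secretase site (Abeta position 17 = 688).
id	start	end	alpha
APP770_HUMAN	672	713	688
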