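# atp1 transcript model on the Arabidopsis Col-0 mitochondrial genome
# (GenBank BK010421). CDS written 5'->3' (reverse strand: start > end).
# The 5'/3' UTR split of the ~520 nt of combined UTR is derived from the
# observed mature transcript (~2044 nt) and cleavage fragment (~280 nt)
# sizes; only the 520-nt total is directly annotated.
gene	strand	cds_start	cds_end	utr5_len	utr3_len
atp1	-	68621	67098	363	157
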