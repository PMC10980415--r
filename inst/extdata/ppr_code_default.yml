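# Default PPR code table: match classes for the canonical P-class
# specifying-residue combinations (the residues often numbered 5 and 35 of
# the 35-amino-acid repeat), assembled from the published PPR-code
# literature. Pairs not listed are treated as neutral for every base.
# Classes: perfect | partial | neutral | mismatch
TD: {A: partial, C: mismatch, G: perfect, U: mismatch}
SD: {A: partial, C: mismatch, G: perfect, U: mismatch}
TN: {A: perfect, C: mismatch, G: partial, U: mismatch}
SN: {A: perfect, C: mismatch, G: partial, U: mismatch}
ND: {A: mismatch, C: partial, G: mismatch, U: perfect}
NN: {A: mismatch, C: partial, G: mismatch, U: perfect}
NS: {A: mismatch, C: perfect, G: mismatch, U: partial}
NT: {A: mismatch, C: perfect, G: mismatch, U: partial}
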