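# Residue template extension example: donor/acceptor annotation for
# modified residues, one atom per line.
# columns: resname  class  atom  role  [hydrogen-name-prefixes]
# role is donor, acceptor or both; hydrogens are comma-separated name
# prefixes matched within the residue (donors only).
#
# carbacyclic fapyG analog (ring-opened base, methylene in place of O4')
CFG	dna	N1	donor	H1
CFG	dna	N2	donor	H21,H22
CFG	dna	O6	acceptor
CFG	dna	N7	donor	H7
CFG	dna	N9	donor	H9
CFG	dna	O1P	acceptor
CFG	dna	O2P	acceptor
CFG	dna	O3'	acceptor
CFG	dna	O5'	acceptor
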