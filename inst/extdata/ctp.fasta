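>CTP rhFSH-CTP C-terminal peptide (hCG beta-subunit CTP, residues 112-139)
SSSSKAPPPSLPSPSRLPGPSDTPILPQ
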