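a1	0	12
msr	12	82
msd	82	170
a2	170	182
canonical_term_site	84	85
branch_g_pos	19	20
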