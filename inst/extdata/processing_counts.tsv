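period	n_locations	n_onland	pct_corrected	pct_removed_interp
1995-2001	15350	3422	90	5
2013-2016	28078	6979	84	12
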