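code	smiles	is_canonical	side_chain_atoms
dA	[*:1]N[C@H](C)C(=O)[*:2]	false	2
dF	[*:1]N[C@H](Cc1ccccc1)C(=O)[*:2]	false	2;3;4;5;6;7;8
Aib	[*:1]NC(C)(C)C(=O)[*:2]	false	2;3
Sar	[*:1]N(C)CC(=O)[*:2]	false	1
MeF	[*:1]N(C)[C@@H](Cc1ccccc1)C(=O)[*:2]	false	1;3;4;5;6;7;8;9
Nle	[*:1]N[C@@H](CCCC)C(=O)[*:2]	false	2;3;4;5
Nva	[*:1]N[C@@H](CCC)C(=O)[*:2]	false	2;3;4
Hse	[*:1]N[C@@H](CCO)C(=O)[*:2]	false	2;3;4
Orn	[*:1]N[C@@H](CCCN)C(=O)[*:2]	false	2;3;4;5
ac	CC(=O)[*:2]	false
am	[*:1]N	false
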