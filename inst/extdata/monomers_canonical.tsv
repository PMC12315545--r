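code	smiles	is_canonical	side_chain_atoms
A	[*:1]N[C@@H](C)C(=O)[*:2]	true	2
R	[*:1]N[C@@H](CCCNC(=N)N)C(=O)[*:2]	true	2;3;4;5;6;7;8
N	[*:1]N[C@@H](CC(N)=O)C(=O)[*:2]	true	2;3;4;5
D	[*:1]N[C@@H](CC(=O)O)C(=O)[*:2]	true	2;3;4;5
C	[*:1]N[C@@H](CS)C(=O)[*:2]	true	2;3
E	[*:1]N[C@@H](CCC(=O)O)C(=O)[*:2]	true	2;3;4;5;6
Q	[*:1]N[C@@H](CCC(N)=O)C(=O)[*:2]	true	2;3;4;5;6
G	[*:1]NCC(=O)[*:2]	true
H	[*:1]N[C@@H](Cc1c[nH]cn1)C(=O)[*:2]	true	2;3;4;5;6;7
I	[*:1]N[C@@H]([C@@H](C)CC)C(=O)[*:2]	true	2;3;4;5
L	[*:1]N[C@@H](CC(C)C)C(=O)[*:2]	true	2;3;4;5
K	[*:1]N[C@@H](CCCCN)C(=O)[*:2]	true	2;3;4;5;6
M	[*:1]N[C@@H](CCSC)C(=O)[*:2]	true	2;3;4;5
F	[*:1]N[C@@H](Cc1ccccc1)C(=O)[*:2]	true	2;3;4;5;6;7;8
P	[*:1]N1CCC[C@H]1C(=O)[*:2]	true	1;2;3
S	[*:1]N[C@@H](CO)C(=O)[*:2]	true	2;3
T	[*:1]N[C@@H]([C@H](O)C)C(=O)[*:2]	true	2;3;4
W	[*:1]N[C@@H](Cc1c[nH]c2ccccc12)C(=O)[*:2]	true	2;3;4;5;6;7;8;9;10;11
Y	[*:1]N[C@@H](Cc1ccc(O)cc1)C(=O)[*:2]	true	2;3;4;5;6;7;8;9
V	[*:1]N[C@@H](C(C)C)C(=O)[*:2]	true	2;3;4
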