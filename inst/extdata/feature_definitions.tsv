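# Default pharmacophore feature definitions.
# Columns: type <TAB> SMARTS <TAB> placement <TAB> directed
# type: A (H-bond acceptor), D (H-bond donor), H (hydrophobe),
#       N (negative ionizable), P (positive ionizable), R (aromatic ring)
# placement: atom (first pattern atom), group_centroid, ring_centroid
# For atom placement the site sits on the first atom of the SMARTS match.
A	[OX2;H0;+0;!$(O=*)]	atom	TRUE
A	[OX2H;+0]	atom	TRUE
A	[OX1;$([OX1]=[#6,#15,#16])]	atom	TRUE
A	[nX2;+0]	atom	TRUE
A	[NX2;+0;!$(N=O);!$(N=N)]	atom	TRUE
A	[NX3;H0;+0;!$(N[C,S,P]=[O,S,N]);!$(N=*)]	atom	TRUE
D	[#7;+0,+1;H1,H2,H3;!$([nX2])]	atom	TRUE
D	[OX2H;+0]	atom	TRUE
D	[SX2H;+0]	atom	TRUE
H	[C;+0;!$(C=[O,N,S]);!$(C#N);!$(C~[N,O,P,F,Cl,Br,I])]	group_centroid	FALSE
H	[c;+0;!$(c~[N,n,O,o])]	group_centroid	FALSE
H	[F,Cl,Br,I;$([F,Cl,Br,I][#6])]	group_centroid	FALSE
N	[CX3](=[OX1])[O-]	group_centroid	FALSE
N	[SX4](=[OX1])(=[OX1])[O-]	group_centroid	FALSE
N	[PX4](=[OX1])[O-]	group_centroid	FALSE
N	c1nnn[n-]1	group_centroid	FALSE
N	[NX2-]	group_centroid	FALSE
P	[#7+;!$([n+])]	group_centroid	FALSE
P	[n+;H]	group_centroid	FALSE
R	a1aaaaa1	ring_centroid	TRUE
R	a1aaaa1	ring_centroid	TRUE
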