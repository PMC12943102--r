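id	smarts
alert_001	*1[O,S,N]*1
alert_002	[S,C](=[O,S])[F,Br,Cl,I]
alert_003	[CX4][Cl,Br,I]
alert_004	[#6]S(=O)(=O)O[#6]
alert_005	[$([CH]),$(CC)]#CC(=O)[#6]
alert_006	[$([CH]),$(CC)]#CC(=O)O[#6]
alert_007	n[OH]
alert_008	[$([CH]),$(CC)]#CS(=O)(=O)[#6]
alert_009	C=C(C=O)C=O
alert_010	n1c([F,Cl,Br,I])cccc1
alert_011	[CH1](=O)
alert_012	[#8][#8]
alert_013	[C;!R]=[N;!R]
alert_014	[N!R]=[N!R]
alert_015	[#6](=O)[#6](=O)
alert_016	[#16][#16]
alert_017	[#7][NH2]
alert_018	C(=O)N[NH2]
alert_019	[#6]=S
alert_020	[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]=[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]
alert_021	C1(=[O,N])C=CC(=[O,N])C=C1
alert_022	C1(=[O,N])C(=[O,N])C=CC=C1
alert_023	a21aa3a(aa1aaaa2)aaaa3
alert_024	a31a(a2a(aa1)aaaa2)aaaa3
alert_025	a1aa2a3a(a1)A=AA=A3=AA=A2
alert_026	c1cc([NH2])ccc1
alert_027	[Hg,Fe,As,Sb,Zn,Se,se,Te,B,Si,Na,Ca,Ge,Ag,Mg,K,Ba,Sr,Be,Ti,Mo,Mn,Ru,Pd,Ni,Cu,Au,Cd,Al,Ga,Sn,Rh,Tl,Bi,Nb,Li,Pb,Hf,Ho]
alert_028	I
alert_029	OS(=O)(=O)[O-]
alert_030	[N+](=O)[O-]
alert_031	C(=O)N[OH]
alert_032	C1NC(=O)NC(=O)1
alert_033	[SH]
alert_034	[S-]
alert_035	c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]
alert_036	c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]
alert_037	[CR1]1[CR1][CR1][CR1][CR1][CR1][CR1]1
alert_038	[CR1]1[CR1][CR1]cc[CR1][CR1]1
alert_039	[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2][CR2]1
alert_040	[CR2]1[CR2][CR2]cc[CR2][CR2][CR2]1
alert_041	[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1
alert_042	[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1
alert_043	C#C
alert_044	[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]
alert_045	[$([N+R]),$([n+R]),$([N+]=C)][O-]
alert_046	[#6]=N[OH]
alert_047	[#6]=NOC=O
alert_048	[#6](=O)[CX4,CR0X3,O][#6](=O)
alert_049	c1ccc2c(c1)ccc(=O)o2
alert_050	[O+,o+,S+,s+]
alert_051	N=C=O
alert_052	[NX3,NX4][F,Cl,Br,I]
alert_053	c1ccccc1OC(=O)[#6]
alert_054	[CR0]=[CR0][CR0]=[CR0]
alert_055	[C+,c+,C-,c-]
alert_056	N=[N+]=[N-]
alert_057	C12C(NC(N1)=O)CSC2
alert_058	c1c([OH])c([OH,NH2,NH])ccc1
alert_059	P
alert_060	[N,O,S]C#N
alert_061	C=C=O
alert_062	[Si][F,Cl,Br,I]
alert_063	[SX2]O
alert_064	[SiR0,CR0](c1ccccc1)(c2ccccc2)(c3ccccc3)
alert_065	O1CCCCC1OC2CCC3CCCCC3C2
alert_066	N=[CR0][N,n,O,S]
alert_067	[cR2]1[cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2][cR2]1[cR2]2[cR2][cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2]2
alert_068	C=[C!r]C#N
alert_069	[cR2]1[cR2]c([N+0X3R0,nX3R0])c([N+0X3R0,nX3R0])[cR2][cR2]1
alert_070	[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2]c([N+0X3R0,nX3R0])[cR2]1
alert_071	[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2][cR2]c1([N+0X3R0,nX3R0])
alert_072	[OH]c1ccc([OH,NH2,NH])cc1
alert_073	c1ccccc1OC(=O)O
alert_074	[SX2H0][N]
alert_075	c12ccccc1(SC(S)=N2)
alert_076	c12ccccc1(SC(=S)N2)
alert_077	c1nnnn1C=O
alert_078	s1c(S)nnc1NC=O
alert_079	S1C=CSC1=S
alert_080	C(=O)Onnn
alert_081	OS(=O)(=O)C(F)(F)F
alert_082	N#CC[OH]
alert_083	N#CC(=O)
alert_084	S(=O)(=O)C#N
alert_085	N[CH2]C#N
alert_086	C1(=O)NCC1
alert_087	S(=O)(=O)[O-,OH]
alert_088	NC[F,Cl,Br,I]
alert_089	C=[C!r]O
alert_090	[NX2+0]=[O+0]
alert_091	[OR0,NR0][OR0,NR0]
alert_092	C(=O)O[C,H1].C(=O)O[C,H1].C(=O)O[C,H1]
alert_093	[CX2R0][NX3R0]
alert_094	c1ccccc1[C;!R]=[C;!R]c2ccccc2
alert_095	[NX3R0,NX4R0,OR0,SX2R0][CX4][NX3R0,NX4R0,OR0,SX2R0]
alert_096	[s,S,c,C,n,N,o,O]~[n+,N+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]
alert_097	[s,S,c,C,n,N,o,O]~[nX3+,NX3+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]
alert_098	[*]=[N+]=[*]
alert_099	[SX3](=O)[O-,OH]
alert_100	N#N
alert_101	F.F.F.F
alert_102	[R0;D2][R0;D2][R0;D2][R0;D2]
alert_103	[cR,CR]~C(=O)NC(=O)~[cR,CR]
alert_104	C=!@CC=[O,S]
alert_105	[#6,#8,#16][#6](=O)O[#6]
alert_106	c[C;R0](=[O,S])[#6]
alert_107	c[SX2][C;!R]
alert_108	C=C=C
alert_109	c1nc([F,Cl,Br,I,S])ncc1
alert_110	c1ncnc([F,Cl,Br,I,S])c1
alert_111	c1nc(c2c(n1)nc(n2)[F,Cl,Br,I])
alert_112	[#6]S(=O)(=O)c1ccc(cc1)F
alert_113	[15N]
alert_114	[13C]
alert_115	[18O]
alert_116	[34S]
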