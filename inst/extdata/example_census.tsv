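protein_id	category	fold_ids
tRNArelatedproteins_P0001	tRNA-related proteins	a.2,c.2
tRNArelatedproteins_P0002	tRNA-related proteins	b.34,c.37,c.55
tRNArelatedproteins_P0003	tRNA-related proteins	b.40,a.2
tRNArelatedproteins_P0004	tRNA-related proteins	c.37
tRNArelatedproteins_P0005	tRNA-related proteins	b.34,c.37
tRNArelatedproteins_P0006	tRNA-related proteins	d.104,d.58
tRNArelatedproteins_P0007	tRNA-related proteins	d.104,d.104
Ribosomalproteins_P0001	Ribosomal proteins	c.2,a.60
Ribosomalproteins_P0002	Ribosomal proteins	b.82,b.43,d.58
Ribosomalproteins_P0003	Ribosomal proteins	d.17,b.82
Ribosomalproteins_P0004	Ribosomal proteins	a.2,c.66
Ribosomalproteins_P0005	Ribosomal proteins	d.17,a.2
Ribosomalproteins_P0006	Ribosomal proteins	c.2
Ribosomalproteins_P0007	Ribosomal proteins	d.17
Ribosomalproteins_P0008	Ribosomal proteins	a.2
Wholeproteome_P0001	Whole proteome	c.26,c.55,a.60
Wholeproteome_P0002	Whole proteome	b.82
Wholeproteome_P0003	Whole proteome	c.66,b.82
Wholeproteome_P0004	Whole proteome	d.15
Wholeproteome_P0005	Whole proteome	b.122,b.43,a.24
Wholeproteome_P0006	Whole proteome	b.82,d.104
Wholeproteome_P0007	Whole proteome	c.108
Wholeproteome_P0008	Whole proteome	d.17
Wholeproteome_P0009	Whole proteome	b.34,c.2
Wholeproteome_P0010	Whole proteome	d.79
Wholeproteome_P0011	Whole proteome	b.43
Wholeproteome_P0012	Whole proteome	e.8,d.58,b.40
Wholeproteome_P0013	Whole proteome	b.34
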