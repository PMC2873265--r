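fold_id	gene_context	specific_function	general_class
c.37	EF-Tu / EF-G	GTP hydrolysis driving elongation	phosphoryl_transfer
b.40	rRNA methyltransferase	base modification of rRNA	rna_modification
d.58	ribosomal protein S4	rRNA binding	rna_binding
a.4	class I ARS	tRNA aminoacylation	other
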