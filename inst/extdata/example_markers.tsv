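fold_id	marker_type
c.2	rnr_catalytic
a.2	domain_restricted
d.104	rnr_catalytic
c.66	domain_restricted
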