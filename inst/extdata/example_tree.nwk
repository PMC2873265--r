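(c.37,(b.40,(d.58,(a.4,(c.2,(d.104,(b.34,(c.26,(a.2,(c.55,(b.43,(d.15,(a.24,(c.66,(b.82,(d.17,(a.60,(c.108,(b.122,(d.79,e.8))))))))))))))))))));
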