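! toy NOE distance restraint table (CNS/XPLOR dialect)
assign (resid 3 and name HA) (resid 7 and name HA) 3.2 1.2 0.8
assign (resid 5 and name H)  (resid 6 and name H)  2.8 1.0 0.7 ! sequential
assign ((resid 10 and name HB1) or (resid 10 and name HB2))
       (resid 14 and name H) 4.0 2.2 1.5
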