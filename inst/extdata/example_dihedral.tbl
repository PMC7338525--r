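! toy backbone dihedral restraints (phi of residue 5, psi of residue 5)
assign (resid 4 and name C) (resid 5 and name N)
       (resid 5 and name CA) (resid 5 and name C) 1.0 -57.0 20.0 2
assign (resid 5 and name N) (resid 5 and name CA)
       (resid 5 and name C) (resid 6 and name N) 1.0 -47.0 25.0 2
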