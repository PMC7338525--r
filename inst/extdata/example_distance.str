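data_toy_restraints

save_distance_constraints
   _Gen_dist_constraint_list.ID   1

   loop_
      _Gen_dist_constraint.ID
      _Gen_dist_constraint.Comp_index_ID_1
      _Gen_dist_constraint.Atom_ID_1
      _Gen_dist_constraint.Comp_index_ID_2
      _Gen_dist_constraint.Atom_ID_2
      _Gen_dist_constraint.Distance_lower_bound_val
      _Gen_dist_constraint.Distance_upper_bound_val

     1   3   HA    7   HA   1.8   4.4
     2   5   H     6   H    1.8   3.5
     3  10   HB1  14   H    1.8   5.5
     3  10   HB2  14   H    1.8   5.5

   stop_
save_
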