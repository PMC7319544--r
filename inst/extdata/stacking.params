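# snvfold 'stacking' energy model (kcal/mol, 37 C)
# Nearest-neighbor model: E(structure) = sum over pairs of the per-pair
# baseline (pair.XY, a terminal-pair-like penalty for AU/GU-type pairs)
# plus one stack term (stack.XY.ZW) for each pair of adjacent nested
# pairs (i,j),(i+1,j-1), where XY are the bases of the outer pair (i,j)
# and ZW those of the inner pair (i+1,j-1).
# Stack free energies adapted from the Watson-Crick and wobble
# nearest-neighbor tables of the Turner lab (37 C RNA parameters);
# the table is completed under helix-flip symmetry
# stack.P1.P2 == stack.rev(P2).rev(P1).
# RT = k_B T in kcal/mol at 37 C.
model = stacking
RT = 0.6163
pair.AU = 0.45
pair.UA = 0.45
pair.CG = 0.0
pair.GC = 0.0
pair.GU = 0.45
pair.UG = 0.45
stack.AU.AU = -0.93
stack.UA.AU = -1.33
stack.CG.AU = -2.11
stack.GC.AU = -2.35
stack.GU.AU = -1.27
stack.UG.AU = -1.00
stack.AU.UA = -1.10
stack.UA.UA = -0.93
stack.CG.UA = -2.08
stack.GC.UA = -2.24
stack.GU.UA = -1.36
stack.UG.UA = -0.55
stack.AU.CG = -2.24
stack.UA.CG = -2.35
stack.CG.CG = -3.26
stack.GC.CG = -3.42
stack.GU.CG = -2.51
stack.UG.CG = -1.53
stack.AU.GC = -2.08
stack.UA.GC = -2.11
stack.CG.GC = -2.36
stack.GC.GC = -3.26
stack.GU.GC = -2.11
stack.UG.GC = -1.41
stack.AU.GU = -0.55
stack.UA.GU = -1.00
stack.CG.GU = -1.41
stack.GC.GU = -1.53
stack.GU.GU = -0.50
stack.UG.GU = 0.30
stack.AU.UG = -1.36
stack.UA.UG = -1.27
stack.CG.UG = -2.11
stack.GC.UG = -2.51
stack.GU.UG = 1.29
stack.UG.UG = -0.50
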