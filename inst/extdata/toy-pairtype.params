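# snvfold 'toy-pairtype' energy model (kcal/mol)
# One energy per canonical pair type; RT = 1 so that Boltzmann weights
# have the closed forms exp(3) for GC, exp(2) for AU, exp(1) for GU.
model = toy-pairtype
RT = 1.0
pair.GC = -3.0
pair.CG = -3.0
pair.AU = -2.0
pair.UA = -2.0
pair.GU = -1.0
pair.UG = -1.0
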