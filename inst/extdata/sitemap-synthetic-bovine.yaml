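species: synthetic-bovine
chains:
  A: alpha
  B: beta
  C: alpha
  D: beta
sites:
  alpha:
    C6:
      resid: 38
      resname: THR
    C7:
      resid: 39
      resname: TYR
    CE4:
      resid: 46
      resname: PHE
    E7:
      resid: 58
      resname: HIS
    E11:
      resid: 62
      resname: VAL
    F8:
      resid: 88
      resname: HIS
    FG4:
      resid: 92
      resname: ARG
    G1:
      resid: 94
      resname: ASP
  beta:
    C6:
      resid: 40
      resname: ARG
    E7:
      resid: 63
      resname: HIS
    F8:
      resid: 92
      resname: HIS
    G4:
      resid: 101
      resname: ASN
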