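# Method configurations for the TCB/LVM binary mixture.
# Wavelengths in nm, concentrations in ug/mL.
methods:
  RS_SS:
    method: RS_SS
    divisor_conc: 5.0
    plateau_region: [290, 306]
    responses:
      TCB: ["D0@304", "D0@220"]
      LVM: ["D0@214"]
  CM_SS:
    method: CM_SS
    divisor_conc: 5.0
    plateau_region: [290, 306]
    responses:
      TCB: ["D0@220", "D0@304"]
      LVM: ["D0@214"]
  FC_SS:
    method: FC_SS
    factorization_ref: 304
    responses:
      TCB: ["D0@220", "D0@304"]
      LVM: ["D0@214"]
  DS_SS:
    method: DS_SS
    divisor_conc: 5.0
    plateau_region: [280, 315]
    responses:
      TCB: ["D1@310", "D1@P228-216"]
      LVM: ["D1@P221"]
  D1CM_SS:
    method: D1CM_SS
    divisor_conc: 5.0
    plateau_region: [280, 315]
    responses:
      TCB: ["D1@P228-216", "D1@310"]
      LVM: ["D1@P221"]
  D1FC_SS:
    method: D1FC_SS
    factorization_ref: 310
    responses:
      TCB: ["D1@P228-216", "D1@310"]
      LVM: ["D1@P221"]
  DD1:
    method: DD1
    divisor_conc:
      LVM: 4.0
      TCB: 3.0
    responses:
      TCB: ["DD1@P230-220"]
      LVM: ["DD1@P219"]
  CV:
    method: CV
    plateau_region: [290, 306]
    responses:
      TCB: ["CV"]
  CNV:
    method: CNV
    plateau_region: [290, 306]
    responses:
      TCB: ["CNV"]
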