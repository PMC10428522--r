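# Analytical Eco-Scale profile of the spectrophotometric procedure:
# methanolic HCl solvent, spectrophotometer, small recycled waste stream.
reagents:
  - name: methanol
    pictograms: 3
    signal_word: danger
    amount_class: "<10"
  - name: HCl
    pictograms: 1
    signal_word: danger
    amount_class: "<10"
energy_class: "<=0.1"
occupational_hazard: false
waste_amount_class: "1-10"
waste_treatment: recycling
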