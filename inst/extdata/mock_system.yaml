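# Example system description for the built-in mock species: 40 planar
# monomers plus 5 cyclic-sulfone inhibitors in a 100 A cubic box. Elements
# are quoted ("N") because bare N/Y parse as booleans under YAML 1.1.
box: [100, 100, 100]
time_step: 1.0
species:
  - name: adenine
    count: 40
    atoms:
      - {name: N1, element: "N", mass: 14.007, ring: true}
      - {name: C2, element: "C", mass: 12.011, ring: true}
      - {name: N3, element: "N", mass: 14.007, ring: true}
      - {name: C4, element: "C", mass: 12.011, ring: true}
      - {name: C5, element: "C", mass: 12.011, ring: true}
      - {name: C6, element: "C", mass: 12.011, ring: true}
      - {name: N7, element: "N", mass: 14.007, ring: true}
      - {name: C8, element: "C", mass: 12.011, ring: true}
      - {name: N9, element: "N", mass: 14.007, ring: true}
      - {name: N10, element: "N", mass: 14.007, hbond: donor}
      - {name: H10, element: "H", mass: 1.008, hbond: hydrogen, donor: N10}
  - name: inhibitor
    count: 5
    atoms:
      - {name: S1, element: "S", mass: 32.06}
      - {name: C1, element: "C", mass: 12.011}
      - {name: C2, element: "C", mass: 12.011}
      - {name: O3, element: "O", mass: 15.999, hbond: acceptor,
         acceptor_class: intra_ring_oxygen}
      - {name: C3, element: "C", mass: 12.011}
      - {name: C4, element: "C", mass: 12.011}
      - {name: O1, element: "O", mass: 15.999, hbond: acceptor,
         acceptor_class: sulfur_bound_oxygen}
      - {name: O2, element: "O", mass: 15.999, hbond: acceptor,
         acceptor_class: sulfur_bound_oxygen}
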