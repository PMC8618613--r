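# Role map for the synthetic monolayer representation: surfactant proxy
# (ESC) with a 2-atom aglycone axis, one donor/hydrogen/acceptor set and
# five inert mass beads; water as a single bead (W) or 3-site (SOL).
roles:
  - {residue: ESC, atom: BAS, role: aglycone_base, mass: 12.011}
  - {residue: ESC, atom: TIP, role: aglycone_tip,  mass: 12.011}
  - {residue: ESC, atom: DON, role: donor,         mass: 15.999}
  - {residue: ESC, atom: HD1, role: hydrogen,      mass: 1.008}
  - {residue: ESC, atom: ACC, role: acceptor,      mass: 15.999}
  - {residue: ESC, atom: M1,  role: other,         mass: 208.795}
  - {residue: ESC, atom: M2,  role: other,         mass: 208.795}
  - {residue: ESC, atom: M3,  role: other,         mass: 208.795}
  - {residue: ESC, atom: M4,  role: other,         mass: 208.795}
  - {residue: ESC, atom: M5,  role: other,         mass: 208.795}
  - {residue: W,   atom: W,   role: water_O,       mass: 18.0154}
  - {residue: SOL, atom: OW,  role: water_O,       mass: 15.999}
  - {residue: SOL, atom: HW1, role: water_H,       mass: 1.008}
  - {residue: SOL, atom: HW2, role: water_H,       mass: 1.008}
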