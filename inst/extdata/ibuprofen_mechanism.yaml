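# Canonical mechanism for the Pd-catalyzed carbonylation route to ibuprofen
# in a perfectly stirred isothermal batch reactor.
#
# Species naming ("H" is the hydronium ion H+, "Cl" the chloride ion Cl-):
#   roh   1-(4-isobutylphenyl)ethanol  (initial substrate, B)
#   ren   4-isobutylstyrene            (dehydration product)
#   rcl   1-chloro-1-(4-isobutylphenyl)ethane
#   ibu   ibuprofen
#   ester ibuprofen / substrate-alcohol ester (side product; carries two
#         aryl backbones, one from ibu and one from roh)
#   pd1   L2PdCl2 catalyst precursor
#   pd2   active reduced Pd complex
#   pd3   aryl-Pd complex after oxidative addition of rcl
#   pd4   acyl-Pd complex after CO insertion (carbonylation)
#   CO    dissolved carbon monoxide, held at saturation (constant)
#
# Reaction steps: r1 alcohol dehydration, r2 alkene hydrohalogenation,
# r3 substrate dehydrohalogenation, r4 catalyst activation, r5 oxidative
# addition, r6 carbonylation, r7 hydrolysis to ibuprofen, r8f/r8r the
# reversible esterification of ibuprofen with the substrate alcohol.
#
# Reactant orders are dictated by the rate-constant units: total order 2
# for m^3/(s*mol), total order 3 for m^6/(s*mol^2).

species: [roh, ren, rcl, ibu, ester, H, Cl, H2O, pd1, pd2, pd3, pd4]

constant_species:
  CO: 1.0

rate_constants:
  k1:  m^3/(s*mol)
  k2:  m^6/(s*mol^2)
  k3:  m^3/(s*mol)
  k4:  m^6/(s*mol^2)
  k5:  m^3/(s*mol)
  k6:  m^3/(s*mol)
  k7:  m^3/(s*mol)
  k8f: m^6/(s*mol^2)
  k8r: m^6/(s*mol^2)

reactions:
  - name: r1          # acid-catalyzed alcohol dehydration
    rate_constant: k1
    orders:        {roh: 1, H: 1}
    stoichiometry: {roh: -1, ren: 1, H2O: 1}
  - name: r2          # alkene hydrohalogenation
    rate_constant: k2
    orders:        {ren: 1, H: 1, Cl: 1}
    stoichiometry: {ren: -1, H: -1, Cl: -1, rcl: 1}
  - name: r3          # substrate dehydrohalogenation, water-mediated
    rate_constant: k3
    orders:        {rcl: 1, H2O: 1}
    stoichiometry: {rcl: -1, H2O: -1, ren: 1, H: 1, Cl: 1}
  - name: r4          # catalyst activation: reduction of the PdCl2 precursor
    rate_constant: k4
    orders:        {pd1: 1, H2O: 2}
    stoichiometry: {pd1: -1, H2O: -1, pd2: 1, H: 2, Cl: 2}
  - name: r5          # oxidative addition of rcl to the active Pd complex
    rate_constant: k5
    orders:        {rcl: 1, pd2: 1}
    stoichiometry: {rcl: -1, pd2: -1, pd3: 1}
  - name: r6          # carbonylation: CO insertion into the aryl-Pd bond
    rate_constant: k6
    orders:        {pd3: 1, CO: 1}
    stoichiometry: {pd3: -1, pd4: 1}
  - name: r7          # hydrolysis of the acyl-Pd complex to ibuprofen
    rate_constant: k7
    orders:        {pd4: 1, H2O: 1}
    stoichiometry: {pd4: -1, H2O: -1, ibu: 1, pd2: 1, H: 1, Cl: 1}
  - name: r8f         # acid-catalyzed esterification of ibuprofen (side reaction)
    rate_constant: k8f
    orders:        {ibu: 1, roh: 1, H: 1}
    stoichiometry: {ibu: -1, roh: -1, ester: 1, H2O: 1}
  - name: r8r         # ester hydrolysis (reverse of r8f)
    rate_constant: k8r
    orders:        {ester: 1, H2O: 1, H: 1}
    stoichiometry: {ester: -1, H2O: -1, ibu: 1, roh: 1}
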