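# Multifiber virtual ligament parameters for the TKA knee model.
#
# `table` lists the final bundle set retained after TKA ligament release
# (superficial MCL, LCL, PCL; ACL/ALL/POL/dMCL are released and absent):
# stiffness in N per unit strain, reference strain in percent at the
# reference pose (knee in full extension). Bundle prefixes: a = anterior,
# am = anterior-middle, m = middle, mp = middle-posterior, p = posterior.
# The am/mp (and middle PCL) bundles are augmentation products: their
# reference strains are the means of the adjacent bundles' values, and
# their insertions lie midway between the adjacent bundles' insertions.
# The middle PCL bundle is generated by the augmentation rule (reference
# strain mean(-28.6, -26.3) = -27.45).
#
# `insertions` gives the original (pre-augmentation) bundle attachment
# sites in mm: femoral points in the femur body frame (origin on the
# flexion axis), tibial points in the tibia body frame (origin on the
# tibial long axis at the joint line); x anterior, y proximal, z lateral
# for a right knee. These are synthetic, anatomically plausible surrogate
# sites (femoral epicondyles, fibular head, distal anteromedial tibia,
# posterior intercondylar tibia), configurable per study.
force_law:
  toe_transition_strain: 0.03
table:
  - {name: aLCL,    ligament: LCL,  stiffness: 1157, reference_strain: -2.66, augmented: false}
  - {name: amLCL,   ligament: LCL,  stiffness: 1171, reference_strain: 0.68,  augmented: true}
  - {name: mLCL,    ligament: LCL,  stiffness: 1175, reference_strain: 4.02,  augmented: false}
  - {name: mpLCL,   ligament: LCL,  stiffness: 1172, reference_strain: 2.66,  augmented: true}
  - {name: pLCL,    ligament: LCL,  stiffness: 1182, reference_strain: 1.29,  augmented: false}
  - {name: a-sMCL,  ligament: sMCL, stiffness: 1469, reference_strain: -4.30, augmented: false}
  - {name: am-sMCL, ligament: sMCL, stiffness: 1603, reference_strain: 0.10,  augmented: true}
  - {name: m-sMCL,  ligament: sMCL, stiffness: 1481, reference_strain: 4.50,  augmented: false}
  - {name: mp-sMCL, ligament: sMCL, stiffness: 1509, reference_strain: 4.47,  augmented: true}
  - {name: p-sMCL,  ligament: sMCL, stiffness: 1105, reference_strain: 4.44,  augmented: false}
  - {name: aPCL,    ligament: PCL,  stiffness: 7841, reference_strain: -28.6, augmented: false}
  - {name: pPCL,    ligament: PCL,  stiffness: 1026, reference_strain: -26.3, augmented: false}
insertions:
  sMCL:
    wrap: [tibia_medial_wrap]
    bundles:
      a-sMCL:  {femur: [4.0, 0.0, -35.0],   tibia: [10.0, -93.0, -17.0]}
      m-sMCL:  {femur: [0.0, 0.0, -35.0],   tibia: [8.0, -95.0, -17.0]}
      p-sMCL:  {femur: [-4.0, 0.0, -35.0],  tibia: [6.0, -97.0, -17.0]}
  LCL:
    wrap: []
    bundles:
      aLCL: {femur: [4.0, 0.0, 41.0],   tibia: [-6.0, -62.0, 30.0]}
      mLCL: {femur: [0.0, 0.0, 41.0],   tibia: [-10.0, -62.0, 30.0]}
      pLCL: {femur: [-4.0, 0.0, 41.0],  tibia: [-14.0, -62.0, 30.0]}
  PCL:
    wrap: []
    bundles:
      aPCL: {femur: [5.0, -13.5, -9.0], tibia: [-23.0, -23.0, -8.0]}
      pPCL: {femur: [3.0, -14.5, -9.0], tibia: [-28.0, -28.0, -8.0]}
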