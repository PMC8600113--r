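# Default tissue material parameters (kPa where dimensional).
#
# Lipid and calcified plaque: isotropic exponential Mooney-Rivlin,
#   W = c1(I1-3) + c2(I2-3) + d1(exp(d2(I1-3)) - 1)
# constants adapted from the Tang et al. carotid/coronary plaque FEA models.
#
# Fibrous intima, media, adventitia: two-term Holzapfel-type anisotropic model,
#   W = mu(I1-3) + k1/k2 (exp{k2[(1-rho)(I1-3)^2 + rho(I4-1)^2]} - 1)
# with a single in-plane circumferential fiber family. mu/k1/k2 adapted from
# the layer-specific human coronary data of Holzapfel et al. (mu transcribed
# as c/2 because this energy carries no 1/2 on the isotropic term; small-strain
# shear modulus G = 2*mu). rho is the in-plane anisotropy weight; 0.85 puts
# most of the exponential stiffening into the fiber direction, which is the
# collagen-dominated regime of those fits.
#
# These are literature defaults, not patient-specific values. Replace the file
# (same layout) and pass it through the run configuration to change them; every
# run echoes the table it used into its manifest.

lipid:
  model: mooney_rivlin
  parameters: {c1: 2.0, c2: 0.0, d1: 2.0, d2: 1.5}
  source: "soft lipid pool, Tang et al. plaque models"
calcium:
  model: mooney_rivlin
  parameters: {c1: 368.0, c2: 0.0, d1: 144.0, d2: 2.0}
  source: "calcification, ~100x fibrous stiffness scale, Tang et al."
fibrous:
  model: holzapfel
  parameters: {mu: 13.95, k1: 263.66, k2: 170.88, rho: 0.85}
  source: "human coronary intima (adaptation of Holzapfel et al. layer data)"
media:
  model: holzapfel
  parameters: {mu: 0.64, k1: 21.60, k2: 8.21, rho: 0.85}
  source: "human coronary media (adaptation of Holzapfel et al. layer data)"
adventitia:
  model: holzapfel
  parameters: {mu: 3.78, k1: 38.57, k2: 85.59, rho: 0.85}
  source: "human coronary adventitia (adaptation of Holzapfel et al. layer data)"
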