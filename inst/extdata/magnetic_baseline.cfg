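# Magnet-assisted IP delivery baseline: 100 nm carriers, 20 x 10 cm
# permanent magnet of 1.5 T remanence, 5 cm from the tumor center.
# Tissue/kinetic/vascular parameters take the package defaults.
label = magnetic-baseline

geometry.R  = 10 mm
geometry.Rn = 0 mm

magnet.length_l   = 20 cm
magnet.height_h   = 10 cm
magnet.distance_d = 5 cm
magnet.B_rem      = 1.5 T
magnet.mu_r       = 1000

particle.radius_a        = 100 nm
particle.chi             = 1
particle.mu0_Msat        = 0.5 T
particle.mobility_scale  = 124.2   # calibrated: penetration half-depth 0.08 cm
particle.hindrance_scale = 160 nm

bc.Pi_outer = 0 Pa
bc.C_outer  = 0.0882 mol/m^3
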