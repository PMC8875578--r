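# Conventional intraperitoneal chemotherapy of a 10 mm peritoneal tumor.
# Omitted fields take the package defaults (tissue and solute-transport
# tables in SI units). No magnet block: no magnetic drift.
label = conventional-ipc

geometry.R  = 10 mm
geometry.Rn = 0 mm

tissue.kappa   = 3e-14          # m^2/Pa/s
tissue.Lp      = 2.10e-11       # m/Pa/s
tissue.SV      = 2e4            # 1/m
tissue.PB      = 2.1e3 Pa
tissue.piB     = 2.7e3 Pa
tissue.pii     = 2e3 Pa
tissue.sigma_s = 0.9
tissue.eta     = 1.12e-3 Pa.s

kinetics.K_ON  = 1.5e2 1/M/s
kinetics.K_OFF = 8e-3 1/s
kinetics.K_INT = 5e-5 1/s
kinetics.C_rec = 1e-5 M
kinetics.phi   = 0.3
kinetics.D_eff = 3.40e-6 cm^2/s
kinetics.omega = 0.4938

vascular.P_perm  = 3.00e-4 cm/s
vascular.sigma_f = 0
vascular.C_p     = 0

bc.Pi_outer = 0 Pa
bc.C_outer  = 0.0882 mol/m^3    # calibrated: 60-min tumor-mean C_F = 0.0013
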