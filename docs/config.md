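# Configuration file schema

`pnpaxon` reads plain-text YAML configuration files.  Every key is optional:
missing keys fall back to the defaults of `default_parameters()`, so an empty
file is a valid configuration.  Units: lengths in metres, concentrations in
mol/m^3 (numerically equal to mM), potentials in volts, times in
milliseconds.

```yaml
constants:            # physical constants
  R: 8.31454          # gas constant, J/(mol K)
  T: 279.450          # temperature, K
  F: 96485            # Faraday constant, C/mol
  eps0: 8.88542e-12   # vacuum permittivity, C/(m V)
  eps_c: 80           # relative permittivity, cytosol/extracellular
  eps_memb: 2         # relative permittivity, membrane

ions:                 # one block per ion: Na, K, Ca, Cl
  Na:
    z: 1              # valence
    D: 1.33e-09       # diffusivity, m^2/s
    n_init_intra: 12  # initial intracellular concentration, mol/m^3
    n_bulk_extra: 145 # initial & top-boundary extracellular concentration
    # alpha (drift coefficient, 1/V) is recomputed as z*F/(R*T) unless set

stepping:
  dt_outer: 0.01      # outer PDE step, ms
  dt_inner_max: 0.0005  # maximal membrane-ODE step, ms
  t_end: 20           # total simulated time, ms
  t_tes_on: 2         # TES activation time, ms (inclusive: phi = 0 at t_tes_on)

tes:
  amplitude: 0.1      # V on the left extracellular boundary once active
  phi_right: 0        # V on the right (ground) boundary

geometry:             # see ?build_domain_spec
  axon_length: 4e-06
  node_length: 1e-06
  membrane_thickness_myelinated: 4.06e-07
  membrane_thickness_node: 5e-09
  intracellular_halfheight: 4.34e-07
  domain_halfheight: 2e-06

mesh:                 # see ?mesh_resolution; or set preset: coarse|full|test
  preset: coarse
  h_bulk: 1.2e-07     # target element size away from the membrane, m
  h_debye: 1e-09      # element size in the refined band at the node faces, m
  debye_band_width: 4e-09
  node_edge_dx: 5e-09 # column width at the node corners, m
  node_nx: 32         # target columns across the node
  membrane_ny: 3      # element layers through the nodal membrane
  grade: 1.5          # geometric growth ratio away from refined bands

membrane:             # gating/conductance registry (see the vignette)
  rate_model: hh1952
  v_shift: 65         # mV
  V_rest: -70.23      # mV
  g_Na: 1200          # S/m^2
  g_K: 360
  g_Ca: 0.2
  # g_Cl is calibrated so net current vanishes at V_rest unless set here

numerics:
  electrodes: open    # "open" (migration passes left/right walls),
                      # "reservoir" (bulk Dirichlet) or "blocking"
  neutral_background: true
  init_double_layers: true
  theta: 1            # theta-rule weight (1 = backward Euler)
  negativity_tol: 0.05
  stabilize_poisson: true
  init_relax_steps: 1500
  init_relax_dt: 0.1  # ms
  init_calib_iters: 2
  init_site_correction: false

output:
  checkpoint_every: 0.5  # ms between field checkpoints

seed: 1               # reserved; the simulation is deterministic
```
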