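# Full-scale microchannel profile: all physical and numerical parameters in SI.
mu: 9.31e-4        # fluid dynamic viscosity (Pa s)
rho: 1000          # fluid density (kg/m^3)
Lx: 1.0e-2         # channel length (m)
Ly: 3.0e-3         # wall separation (m)
h: 4.17e-5         # Eulerian grid spacing (m)
ds: 8.33e-6        # Lagrangian biofilm spacing (m), h/5
dt: 1.0e-3         # time step (s)
E: 50              # elastic modulus (Pa)
eta: 5.0e+4         # dashpot viscosity (Pa s); "infinite" selects Stokes elements
eta_water: 1.02e+3  # fluid-drag viscosity correction (Pa s)
A: 8.33e-2         # wall neighbor-spring stiffness (N/m)
B: 6.25e-2         # wall tether stiffness (N/m)
C: 6.25e-2         # biofilm bottom-node tether stiffness (N/m)
D: 8.33e-2         # freeze tether stiffness (N/m)
d_w: 2.083e-5      # wall node spacing (m), h/2
r_c: 1.5e-4        # initial biofilm radius (m)
u_max: 5.0e-6      # target maximum channel speed (m/s)
c0: 1.0e-3         # source concentration (kg/m^3)
D_c: 1.0e-10       # nutrient diffusivity (m^2/s)
mu_max: 2.0e-4     # maximum specific growth rate (1/s)
K: 1.0e-4          # half-saturation constant (kg/m^3)
"Y": 0.553           # yield coefficient
lambda_b: 1120     # bacterial mass density (kg/m^3)
v0: 1.75e-18       # bacterium volume (m^3)
n0: 2.1e+17         # bacterial number density (1/m^3)
chi: 1.0e-6        # slab thickness (m)
nutrient_config: none
t_freeze: 20       # flow-development hold (s)
t_end: 9000        # total simulated time (s)
seed: 1
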