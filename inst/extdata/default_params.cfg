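# Default coupled STEN-CEN model parameters (nondimensional units).
# STEN: slow excitable activator-inhibitor pair, organises travelling waves.
d_fs  = 0.5
d_rs  = 1.0
a1s   = 0.5
a2s   = 1.0
a3s   = 4.0
a4s   = 1.0
a5s   = 0.02
eps_s = 0.05
c1s   = 5.0
u_b   = 0.2
# r0 is the resting inhibitor level of this STEN set (equilibrium of the
# reaction system), used as the reference in the STEN-to-CEN coupling.
r0    = 0.186073974114

# CEN: same architecture, eight-fold faster inhibitor (eps_c/eps_s = 8),
# weak diffusion so firings stay spatially confined.
d_fc    = 0.05
d_rc    = 0.05
a1c     = 0.5
a2c     = 1.0
a3c     = 4.0
a4c     = 1.0
a5c     = 0.02
eps_c   = 0.4
c1c     = 5.0
s_c     = 1.0
sigma_c = 0.4

# CEN-to-STEN feedback: fast local positive loop (Z_C), slow global
# negative loop (W_C); steady-state gain ratio (p4/p3)/(p2/p1) = 2.
d_zc = 0.05
d_wc = Inf
p1   = 1.0
p2   = 0.08
p3   = 0.05
p4   = 0.008
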