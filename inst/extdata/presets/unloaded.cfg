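# mesosaxs preset: unloaded fluorinated-amphiphile dispersion (hexosome/cubosome)
# Printed structural targets. Shape parameters are back-computed on load:
#   Rg1 = Rc/sqrt(2); Rg2 = sqrt((L^2 + 6*Rc^2)/12)
#   q_peak = 4*pi/(sqrt(3)*a); sigma = 2*pi/l_c
#   peak area k = contrast * (continuum at q_peak) * pi * sigma
# Scales (G, G1, background, contrast) are stated package defaults: printed
# values constrain shapes, not absolute intensities.
name = unloaded
Rg = 20.0
Rc = 1.27
L = 20.3
a1 = 6.42
lc1 = 67
a2 = 7.72
lc2 = 67
d = 4
G = 1
G1 = 0.01
background = 1e-4
contrast1 = 10
contrast2 = 5
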