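# mesosaxs preset: LEF-loaded fluorinated-amphiphile hexosomes
name = LEF
Rg = 26.6
Rc = 1.09
L = 20.6
a1 = 6.48
lc1 = 33
d = 4
G = 1
G1 = 0.01
background = 1e-4
contrast1 = 10
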