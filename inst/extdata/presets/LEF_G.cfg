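# mesosaxs preset: LEF G-loaded fluorinated-amphiphile hexosomes
name = LEF_G
Rg = 30.3
Rc = 1.13
L = 18.7
a1 = 6.48
lc1 = 65
d = 4
G = 1
G1 = 0.01
background = 1e-4
contrast1 = 10
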