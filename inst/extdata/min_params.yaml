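# Canonical Min skeleton model parameters (units: um, s)
Dc: 60        # bulk diffusion [um^2/s]
Dm: 0.013     # membrane diffusion [um^2/s]
nD_bar: 665   # average total MinD density [um^-3]
nE_bar: 410   # average total MinE density [um^-3]
kD: 0.065     # MinD attachment rate [um/s]
kdD: 0.098    # MinD recruitment rate [um^3/s]
kdE: 0.126    # MinE recruitment rate [um^3/s]
kde: 0.34     # MinDE dissociation rate [1/s]
lam: 6        # nucleotide exchange rate [1/s]
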