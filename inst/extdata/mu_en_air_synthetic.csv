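"energy_keV","mu_en_over_rho_m2_per_kg"
10,0.4742
12.5,0.235956
15,0.1334
17.5,0.0820776
20,0.05389
22.5,0.0374317
25,0.0270187
27.5,0.0201184
30,0.01537
32.5,0.0122664
35,0.00995465
37.5,0.00819583
40,0.006833
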