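"energy_keV","hvl_mm"
10,0.0979094
12.5,0.188794
15,0.322836
17.5,0.505828
20,0.746342
22.5,1.03191
25,1.37882
27.5,1.79212
30,2.27674
32.5,2.75492
35,3.28675
37.5,3.87377
40,4.51744
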