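"energy_keV","thickness_cm","glandularity","dgn_mgy_per_r"
15,3,0,0.315668
20,3,0,0.602638
25,3,0,0.860912
30,3,0,1.11918
35,3,0,1.32006
15,4,0,0.265624
20,4,0,0.5071
25,4,0,0.724428
30,4,0,0.941757
35,4,0,1.11079
15,4.5,0,0.2475
20,4.5,0,0.4725
25,4.5,0,0.675
30,4.5,0,0.8775
35,4.5,0,1.035
15,5,0,0.232338
20,5,0,0.443555
25,5,0,0.63365
30,5,0,0.823745
35,5,0,0.971596
15,6,0,0.208263
20,6,0,0.397593
25,6,0,0.56799
30,6,0,0.738387
35,6,0,0.870918
15,7,0,0.189865
20,7,0,0.362469
25,7,0,0.517812
30,7,0,0.673156
35,7,0,0.793979
15,3,0.25,0.29813
20,3,0.25,0.569158
25,3,0.25,0.813083
30,3,0.25,1.05701
35,3,0.25,1.24673
15,4,0.25,0.250867
20,4,0.25,0.478927
25,4,0.25,0.684182
30,4,0.25,0.889437
35,4,0.25,1.04908
15,4.5,0.25,0.23375
20,4.5,0.25,0.44625
25,4.5,0.25,0.6375
30,4.5,0.25,0.82875
35,4.5,0.25,0.9775
15,5,0.25,0.219431
20,5,0.25,0.418913
25,5,0.25,0.598447
30,5,0.25,0.777981
35,5,0.25,0.917619
15,6,0.25,0.196693
20,6,0.25,0.375504
25,6,0.25,0.536435
30,6,0.25,0.697365
35,6,0.25,0.822533
15,7,0.25,0.179317
20,7,0.25,0.342332
25,7,0.25,0.489045
30,7,0.25,0.635759
35,7,0.25,0.749869
15,3,0.5,0.280593
20,3,0.5,0.535678
25,3,0.5,0.765255
30,3,0.5,0.994831
35,3,0.5,1.17339
15,4,0.5,0.23611
20,4,0.5,0.450755
25,4,0.5,0.643936
30,4,0.5,0.837117
35,4,0.5,0.987369
15,4.5,0.5,0.22
20,4.5,0.5,0.42
25,4.5,0.5,0.6
30,4.5,0.5,0.78
35,4.5,0.5,0.92
15,5,0.5,0.206523
20,5,0.5,0.394271
25,5,0.5,0.563244
30,5,0.5,0.732218
35,5,0.5,0.863641
15,6,0.5,0.185123
20,6,0.5,0.353416
25,6,0.5,0.50488
30,6,0.5,0.656344
35,6,0.5,0.774149
15,7,0.5,0.168768
20,7,0.5,0.322194
25,7,0.5,0.460278
30,7,0.5,0.598361
35,7,0.5,0.705759
15,3,0.75,0.263056
20,3,0.75,0.502198
25,3,0.75,0.717426
30,3,0.75,0.932654
35,3,0.75,1.10005
15,4,0.75,0.221353
20,4,0.75,0.422583
25,4,0.75,0.60369
30,4,0.75,0.784797
35,4,0.75,0.925658
15,4.5,0.75,0.20625
20,4.5,0.75,0.39375
25,4.5,0.75,0.5625
30,4.5,0.75,0.73125
35,4.5,0.75,0.8625
15,5,0.75,0.193615
20,5,0.75,0.369629
25,5,0.75,0.528041
30,5,0.75,0.686454
35,5,0.75,0.809664
15,6,0.75,0.173552
20,6,0.75,0.331327
25,6,0.75,0.473325
30,6,0.75,0.615322
35,6,0.75,0.725765
15,7,0.75,0.15822
20,7,0.75,0.302057
25,7,0.75,0.43151
30,7,0.75,0.560963
35,7,0.75,0.661649
15,3,1,0.245519
20,3,1,0.468719
25,3,1,0.669598
30,3,1,0.870477
35,3,1,1.02672
15,4,1,0.206596
20,4,1,0.394411
25,4,1,0.563444
30,4,1,0.732477
35,4,1,0.863948
15,4.5,1,0.1925
20,4.5,1,0.3675
25,4.5,1,0.525
30,4.5,1,0.6825
35,4.5,1,0.805
15,5,1,0.180708
20,5,1,0.344987
25,5,1,0.492839
30,5,1,0.64069
35,5,1,0.755686
15,6,1,0.161982
20,6,1,0.309239
25,6,1,0.44177
30,6,1,0.574301
35,6,1,0.67738
15,7,1,0.147672
20,7,1,0.28192
25,7,1,0.402743
30,7,1,0.523566
35,7,1,0.617539
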