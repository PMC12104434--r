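age_lower,intercept,coeff_stature,coeff_mass,coeff_midparent
4.0,-3.97,0.78,0.03,0.6
4.5,-4.287,0.787,0.029,0.587
5.0,-4.635,0.793,0.028,0.575
5.5,-4.963,0.8,0.027,0.562
6.0,-5.366,0.807,0.026,0.55
6.5,-5.661,0.813,0.025,0.537
7.0,-6.007,0.82,0.024,0.524
7.5,-6.428,0.827,0.023,0.512
8.0,-6.738,0.833,0.022,0.499
8.5,-7.17,0.84,0.021,0.487
9.0,-7.54,0.847,0.02,0.474
9.5,-7.865,0.853,0.019,0.461
10.0,-8.315,0.86,0.018,0.449
10.5,-8.704,0.867,0.017,0.436
11.0,-9.016,0.873,0.015,0.424
11.5,-9.412,0.88,0.014,0.411
12.0,-9.882,0.887,0.013,0.399
12.5,-10.232,0.893,0.012,0.386
13.0,-10.646,0.9,0.011,0.373
13.5,-11.134,0.907,0.01,0.361
14.0,-11.499,0.913,0.009,0.348
14.5,-11.999,0.92,0.008,0.336
15.0,-12.437,0.927,0.007,0.323
15.5,-12.816,0.933,0.006,0.31
16.0,-13.334,0.94,0.005,0.298
16.5,-13.79,0.947,0.004,0.285
17.0,-14.252,0.953,0.003,0.273
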