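name element x y z charge epsilon rmin_half mass
C1 C -2.5716 0.3552 0.2508 -0.0007 0.07 2.0 12.011
N1 N -1.9222 -0.8801 0.6745 -0.2135 0.17 1.85 14.007
S1 S -0.6391 -1.4735 -0.2381 0.2493 0.3 2.0 32.067
O1 O -1.0130 -1.4854 -1.6332 -0.2063 0.15 1.7 15.999
O2 O -0.1836 -2.6641 0.4471 -0.2063 0.15 1.7 15.999
C2 C 0.7234 -0.3351 -0.0700 0.1344 0.07 2.0 12.011
C3 C 1.8360 -0.3541 0.7520 -0.0311 0.07 2.0 12.011
C4 C 2.6777 0.7787 0.5574 -0.0501 0.07 2.0 12.011
C5 C 2.1809 1.6264 -0.4072 -0.0079 0.07 2.0 12.011
S2 S 0.7108 1.0545 -1.0692 -0.1310 0.3 2.0 32.067
H1 H -3.5606 0.4079 0.7160 0.0403 0.03 1.2 1.008
H2 H -2.7131 0.3916 -0.8320 0.0403 0.03 1.2 1.008
H3 H -1.9985 1.2230 0.5858 0.0403 0.03 1.2 1.008
H4 H -1.7744 -1.0000 1.6752 0.1405 0.03 1.2 1.008
H5 H 2.0322 -1.1576 1.4531 0.0646 0.03 1.2 1.008
H6 H 3.6027 0.9592 1.0922 0.0632 0.03 1.2 1.008
H7 H 2.6123 2.5533 -0.7611 0.0740 0.03 1.2 1.008
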