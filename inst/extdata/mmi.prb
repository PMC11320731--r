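name element x y z charge epsilon rmin_half mass
C1 C 3.6137 -0.7313 -0.3583 0.0775 0.07 2.0 12.011
O1 O 2.2645 -1.1771 -0.3916 -0.4960 0.15 1.7 15.999
C2 C 1.2904 -0.2383 -0.1852 0.1294 0.07 2.0 12.011
C3 C 1.5142 1.1267 0.0564 -0.0191 0.07 2.0 12.011
C4 C 0.4514 2.0136 0.2565 -0.0564 0.07 2.0 12.011
C5 C -0.8751 1.5775 0.2242 -0.0359 0.07 2.0 12.011
C6 C -1.0922 0.2162 -0.0169 0.0716 0.07 2.0 12.011
N1 N -2.2390 -0.5354 -0.1134 -0.2678 0.17 1.85 14.007
C7 C -3.5927 -0.0537 0.0231 0.0304 0.07 2.0 12.011
N2 N -2.0219 -1.8420 -0.3600 -0.1804 0.17 1.85 14.007
C8 C -0.6905 -1.9260 -0.4229 0.0606 0.07 2.0 12.011
C9 C -0.0478 -0.6833 -0.2187 0.0619 0.07 2.0 12.011
H1 H 3.8718 -0.3264 0.6258 0.0669 0.03 1.2 1.008
H2 H 4.2566 -1.5981 -0.5398 0.0669 0.03 1.2 1.008
H3 H 3.8083 -0.0015 -1.1511 0.0669 0.03 1.2 1.008
H4 H 2.5196 1.5343 0.0950 0.0662 0.03 1.2 1.008
H5 H 0.6618 3.0652 0.4413 0.0625 0.03 1.2 1.008
H6 H -1.6948 2.2707 0.3803 0.0646 0.03 1.2 1.008
H7 H -4.2924 -0.8839 -0.1042 0.0479 0.03 1.2 1.008
H8 H -3.7695 0.7014 -0.7468 0.0479 0.03 1.2 1.008
H9 H -3.7066 0.3775 1.0207 0.0479 0.03 1.2 1.008
H10 H -0.2299 -2.8862 -0.6150 0.0868 0.03 1.2 1.008
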