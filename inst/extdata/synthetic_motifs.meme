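MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.321 C 0.179 G 0.179 T 0.321

MOTIF TATA_synthetic
letter-probability matrix: alength= 4 w= 8 nsites= 100 E= 0
 0.020000 0.020000 0.020000 0.940000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.940000 0.020000 0.020000 0.020000
 0.480000 0.020000 0.020000 0.480000
 0.940000 0.020000 0.020000 0.020000
 0.480000 0.020000 0.020000 0.480000
 0.480000 0.020000 0.480000 0.020000

MOTIF SS5_donor_synthetic
letter-probability matrix: alength= 4 w= 9 nsites= 100 E= 0
 0.300000 0.350000 0.200000 0.150000
 0.600000 0.100000 0.200000 0.100000
 0.100000 0.050000 0.800000 0.050000
 0.000000 0.000000 1.000000 0.000000
 0.000000 0.000000 0.000000 1.000000
 0.500000 0.020000 0.450000 0.030000
 0.700000 0.050000 0.150000 0.100000
 0.100000 0.050000 0.800000 0.050000
 0.050000 0.050000 0.050000 0.850000
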