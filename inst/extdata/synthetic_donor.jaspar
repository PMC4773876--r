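>SD_synth SS5_donor_synthetic
A [ 30 60 10 0 0 50 70 10 5 ]
C [ 35 10 5 0 0 2 5 5 5 ]
G [ 20 20 80 100 0 45 15 80 5 ]
T [ 15 10 5 0 100 3 10 5 85 ]
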