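amino_acid,value
Ala,1.8
Arg,-4.5
Asp,-3.5
Asn,-3.5
Cys,2.5
Glu,-3.5
Gln,-3.5
Gly,-0.4
His,-3.2
Ile,4.5
Leu,3.8
Lys,-3.9
Met,1.9
Phe,2.8
Pro,-1.6
Ser,-0.8
Thr,-0.7
Trp,-0.9
Tyr,-1.3
Val,4.2
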