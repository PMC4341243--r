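amino_acid,value
Ala,7
Arg,9.1
Asp,13
Asn,10
Cys,4.8
Glu,12.5
Gln,8.6
Gly,7.9
His,8.4
Ile,4.9
Leu,4.9
Lys,10.1
Met,5.3
Phe,5
Pro,6.6
Ser,7.5
Thr,6.6
Trp,5.2
Tyr,5.4
Val,5.6
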