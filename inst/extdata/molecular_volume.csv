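amino_acid,value
Ala,31
Arg,124
Asp,54
Asn,56
Cys,55
Glu,83
Gln,85
Gly,3
His,96
Ile,111
Leu,111
Lys,119
Met,105
Phe,132
Pro,32.5
Ser,32
Thr,61
Trp,170
Tyr,136
Val,84
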