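analyte,threshold,taste_class,reconstructed
Asp,80,umami,FALSE
Thr,2600,sweet,FALSE
Ser,1500,sweet,FALSE
Glu,110,umami,FALSE
Gly,2160,umami,FALSE
Ala,1500,umami,FALSE
Cys,NA,bitter,FALSE
Val,400,bitter,FALSE
Met,300,bitter,FALSE
Ile,900,bitter,FALSE
Leu,5500,bitter,FALSE
Tyr,NA,aromatic,FALSE
Phe,530,aromatic,FALSE
His,200,bitter,FALSE
Lys,500,,FALSE
Arg,500,sweet;bitter,TRUE
Pro,3000,sweet,FALSE
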