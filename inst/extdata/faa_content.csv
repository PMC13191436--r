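analyte,group,value,sd
Asp,A,242.34,0.06
Thr,A,215.3,0.32
Ser,A,197.5,0.42
Glu,A,1226.62,0.08
Gly,A,97.53,0.38
Ala,A,431.53,0.09
Cys,A,33.4,0.07
Val,A,152.54,0.1
Met,A,34.76,0.07
Ile,A,98.75,0.1
Leu,A,168.65,0.01
Tyr,A,79.32,0.59
Phe,A,106.54,0.06
His,A,253.1,0.18
Lys,A,137.72,0.01
Arg,A,469.64,0.05
Pro,A,94.37,0.05
Asp,B,226.52,0.22
Thr,B,215.75,0.08
Ser,B,192.27,0.14
Glu,B,1174.41,0.05
Gly,B,82.81,0.15
Ala,B,446.36,0.15
Cys,B,39.6,0.08
Val,B,160.51,0.1
Met,B,36.23,0.22
Ile,B,99.42,0.13
Leu,B,181.2,0.01
Tyr,B,89.3,0.08
Phe,B,107.43,0.06
His,B,264.1,0.07
Lys,B,139.53,0.06
Arg,B,406.23,0.05
Pro,B,95.11,0.09
Asp,C,212.64,0.21
Thr,C,214.12,0.02
Ser,C,189.11,0.2
Glu,C,1142.34,0.11
Gly,C,83.75,0.14
Ala,C,439.93,0.09
Cys,C,31.95,0.06
Val,C,153.31,0.01
Met,C,32.28,0.04
Ile,C,147.21,0.02
Leu,C,167.46,0.03
Tyr,C,82.45,0.04
Phe,C,98.36,0.04
His,C,273.72,0.07
Lys,C,131.53,0.03
Arg,C,369.12,0.04
Pro,C,95.12,0.02
Asp,D,232.73,0.01
Thr,D,211.4,0.53
Ser,D,191.11,0.26
Glu,D,1191.36,0.33
Gly,D,84.21,0.09
Ala,D,426.52,0.11
Cys,D,34.74,0.04
Val,D,147.08,0.03
Met,D,24.03,0.02
Ile,D,99.42,0.01
Leu,D,168.62,0.01
Tyr,D,83.52,0.01
Phe,D,101.82,0.01
His,D,326.12,0.01
Lys,D,128.81,0.03
Arg,D,378.05,0.24
Pro,D,91.21,0.09
Asp,E,257.52,0.1
Thr,E,233.52,0.51
Ser,E,212.81,0.01
Glu,E,1287.13,0.02
Gly,E,85.14,0.05
Ala,E,462.74,0.08
Cys,E,31.64,0.1
Val,E,168.51,0.03
Met,E,33.81,0.03
Ile,E,111.13,0.11
Leu,E,189.15,0.04
Tyr,E,79.82,0.02
Phe,E,111.2,0.02
His,E,313.87,0.04
Lys,E,152.41,0.01
Arg,E,528.12,0.03
Pro,E,99.13,0.02
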