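Residue: Ala
Variant: standard
Nucleus: N15
Delta0: 124.39
B1: 2.74
B1Err: 0.03
B2: -1.49
B2Err: 0.16
OneJHN: -97.5

Residue: Arg
Variant: standard
Nucleus: N15
Delta0: 121
B1: 3.01
B1Err: 0.04
B2: -2.44
B2Err: 0.21
OneJHN: -95.5

Residue: Asn
Variant: standard
Nucleus: N15
Delta0: 119.12
B1: 2.98
B1Err: 0.17
B2: -1.73
B2Err: 0.82
OneJHN: -95.9

Residue: Asp
Variant: standard
Nucleus: N15
Delta0: 120.94
B1: 2.94
B1Err: 0.07
B2: -2.58
B2Err: 0.36
OneJHN: -96

Residue: Cys
Variant: standard
Nucleus: N15
Delta0: 119.21
B1: 2.75
B1Err: 0.08
B2: -1.87
B2Err: 0.41
OneJHN: -96

Residue: Gln
Variant: standard
Nucleus: N15
Delta0: 120.25
B1: 2.87
B1Err: 0.06
B2: -2.15
B2Err: 0.29
OneJHN: -93.5

Residue: Glu
Variant: standard
Nucleus: N15
Delta0: 120.95
B1: 2.78
B1Err: 0.17
B2: -1.66
B2Err: 0.83
OneJHN: -99.5

Residue: Gly
Variant: standard
Nucleus: N15
Delta0: 109.22
B1: 3.79
B1Err: 0.08
B2: -2.16
B2Err: 0.37
OneJHN: -96.9

Residue: His
Variant: pH4.0
Nucleus: N15
Delta0: 118.34
B1: 3.42
B1Err: 0.08
B2: -2.86
B2Err: 0.38
OneJHN: -98.2

Residue: His
Variant: pH8.5
Nucleus: N15
Delta0: 120.33
B1: 3.15
B1Err: 0.1
B2: -3.53
B2Err: 0.5

Residue: Ile
Variant: standard
Nucleus: N15
Delta0: 120.39
B1: 2.35
B1Err: 0.03
B2: -1.89
B2Err: 0.17
OneJHN: -92.9

Residue: Leu
Variant: standard
Nucleus: N15
Delta0: 122.07
B1: 2.65
B1Err: 0.1
B2: -2.92
B2Err: 0.48
OneJHN: -96.2

Residue: Lys
Variant: standard
Nucleus: N15
Delta0: 121.29
B1: 3
B1Err: 0.03
B2: -2.24
B2Err: 0.13
OneJHN: -94.7

Residue: Met
Variant: standard
Nucleus: N15
Delta0: 120.17
B1: 2.76
B1Err: 0.05
B2: -1.89
B2Err: 0.22
OneJHN: -92.7

Residue: Phe
Variant: standard
Nucleus: N15
Delta0: 120.62
B1: 3.01
B1Err: 0.04
B2: -3.65
B2Err: 0.19
OneJHN: -95.5

Residue: Pro
Variant: trans
Nucleus: N15
Delta0: 134.78
B1: 2.45
B1Err: 0.02
B2: -1.76
B2Err: 0.1

Residue: Pro
Variant: cis
Nucleus: N15
Delta0: 135.03
B1: 1.36
B1Err: 0.02
B2: -0.38
B2Err: 0.1

Residue: Ser
Variant: standard
Nucleus: N15
Delta0: 116.27
B1: 3.41
B1Err: 0.15
B2: -2.46
B2Err: 0.7
OneJHN: -95.7

Residue: Thr
Variant: standard
Nucleus: N15
Delta0: 114.14
B1: 3.28
B1Err: 0.05
B2: -2.36
B2Err: 0.24
OneJHN: -93.8

Residue: Trp
Variant: standard
Nucleus: N15
Delta0: 121.43
B1: 3.35
B1Err: 0.03
B2: -2.9
B2Err: 0.17
OneJHN: -95.5

Residue: Tyr
Variant: standard
Nucleus: N15
Delta0: 120.33
B1: 3.56
B1Err: 0.07
B2: -4.52
B2Err: 0.32
OneJHN: -93.9

Residue: Val
Variant: standard
Nucleus: N15
Delta0: 119.41
B1: 2.32
B1Err: 0.02
B2: -1.7
B2Err: 0.12
OneJHN: -95

Residue: Ala
Variant: standard
Nucleus: H1N
Delta0: 8.368
B1: 0.45
B1Err: 0.02
B2: -0.15
B2Err: 0.08

Residue: Arg
Variant: standard
Nucleus: H1N
Delta0: 8.342
B1: 0.48
B1Err: 0.02
B2: -0.22
B2Err: 0.1

Residue: Asn
Variant: standard
Nucleus: H1N
Delta0: 8.503
B1: 0.5
B1Err: 0.03
B2: -0.42
B2Err: 0.14

Residue: Asp
Variant: standard
Nucleus: H1N
Delta0: 8.433
B1: 0.56
B1Err: 0.02
B2: -0.48
B2Err: 0.09

Residue: Cys
Variant: standard
Nucleus: H1N
Delta0: 8.418
B1: 0.55
B1Err: 0.01
B2: -0.49
B2Err: 0.05

Residue: Gln
Variant: standard
Nucleus: H1N
Delta0: 8.433
B1: 0.44
B1Err: 0.03
B2: -0.17
B2Err: 0.13

Residue: Glu
Variant: standard
Nucleus: H1N
Delta0: 8.539
B1: 0.25
B1Err: 0.02
B2: -0.03
B2Err: 0.08

Residue: Gly
Variant: standard
Nucleus: H1N
Delta0: 8.449
B1: 0.24
B1Err: 0.01
B2: -0.1
B2Err: 0.06

Residue: His
Variant: pH4.0
Nucleus: H1N
Delta0: 8.484
B1: 0.51
B1Err: 0.01
B2: -0.47
B2Err: 0.06

Residue: Ile
Variant: standard
Nucleus: H1N
Delta0: 8.154
B1: 0.64
B1Err: 0.03
B2: -0.64
B2Err: 0.14

Residue: Leu
Variant: standard
Nucleus: H1N
Delta0: 8.279
B1: 0.52
B1Err: 0.02
B2: -0.5
B2Err: 0.12

Residue: Lys
Variant: standard
Nucleus: H1N
Delta0: 8.317
B1: 0.55
B1Err: 0.02
B2: -0.49
B2Err: 0.1

Residue: Met
Variant: standard
Nucleus: H1N
Delta0: 8.398
B1: 0.49
B1Err: 0.02
B2: -0.31
B2Err: 0.1

Residue: Phe
Variant: standard
Nucleus: H1N
Delta0: 8.263
B1: 0.55
B1Err: 0.02
B2: -0.68
B2Err: 0.1

Residue: Ser
Variant: standard
Nucleus: H1N
Delta0: 8.434
B1: 0.64
B1Err: 0.05
B2: -0.65
B2Err: 0.26

Residue: Thr
Variant: standard
Nucleus: H1N
Delta0: 8.269
B1: 0.75
B1Err: 0.02
B2: -0.56
B2Err: 0.11

Residue: Trp
Variant: standard
Nucleus: H1N
Delta0: 8.129
B1: 0.58
B1Err: 0.02
B2: -0.42
B2Err: 0.11

Residue: Tyr
Variant: standard
Nucleus: H1N
Delta0: 8.19
B1: 0.67
B1Err: 0.05
B2: -0.82
B2Err: 0.25

Residue: Val
Variant: standard
Nucleus: H1N
Delta0: 8.232
B1: 0.58
B1Err: 0.02
B2: -0.21
B2Err: 0.08
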