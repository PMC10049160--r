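label	class	area_km2
2020	farmland	73615.78
2020	forests	160449.22
2020	grassland	13568.41
2020	wetland	4416.96
2020	waters	4561.83
2020	construction	6580.18
2020	unused	30.46
2030_NES	farmland	72698.53
2030_NES	forests	160364.60
2030_NES	grassland	13199.58
2030_NES	wetland	4567.22
2030_NES	waters	4655.35
2030_NES	construction	7707.39
2030_NES	unused	30.17
2030_EPS	farmland	72643.50
2030_EPS	forests	160570.26
2030_EPS	grassland	13785.44
2030_EPS	wetland	4682.18
2030_EPS	waters	4737.22
2030_EPS	construction	6775.37
2030_EPS	unused	28.87
2030_EDS	farmland	72861.43
2030_EDS	forests	160279.99
2030_EDS	grassland	13015.16
2030_EDS	wetland	4448.08
2030_EDS	waters	4561.83
2030_EDS	construction	8031.38
2030_EDS	unused	24.97
2030_PDS	farmland	72707.71
2030_PDS	forests	160496.34
2030_PDS	grassland	13207.69
2030_PDS	wetland	4468.54
2030_PDS	waters	4570.83
2030_PDS	construction	7743.02
2030_PDS	unused	28.71
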