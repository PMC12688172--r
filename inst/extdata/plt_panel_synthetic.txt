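# Synthetic stand-in platelet (PLT) marker exclusion panel.
# A core of genuine marker gene symbols padded with synthetic symbols to
# the published cluster size; replace with the real cluster list for
# analyses of real data. One symbol per line.
PF4
PF4V1
PPBP
ITGA2B
ITGB3
GP1BA
GP1BB
GP5
GP6
GP9
VWF
THBS1
SELP
TUBB1
MYL9
TREML1
CLU
NRGN
CAVIN2
SPARC
PDGFA
PDGFB
CD9
TLN1
F13A1
CLEC1B
MMRN1
PTGS1
LTBP1
CMTM5
PROS1
LGALSL
MPIG6B
PLEK
RGS18
TMEM40
PLTSYN001
PLTSYN002
PLTSYN003
PLTSYN004
PLTSYN005
PLTSYN006
PLTSYN007
PLTSYN008
PLTSYN009
PLTSYN010
PLTSYN011
PLTSYN012
PLTSYN013
PLTSYN014
PLTSYN015
PLTSYN016
PLTSYN017
PLTSYN018
PLTSYN019
PLTSYN020
PLTSYN021
PLTSYN022
PLTSYN023
PLTSYN024
PLTSYN025
PLTSYN026
PLTSYN027
PLTSYN028
PLTSYN029
PLTSYN030
PLTSYN031
PLTSYN032
PLTSYN033
PLTSYN034
PLTSYN035
PLTSYN036
PLTSYN037
PLTSYN038
PLTSYN039
PLTSYN040
PLTSYN041
PLTSYN042
PLTSYN043
PLTSYN044
PLTSYN045
PLTSYN046
PLTSYN047
PLTSYN048
PLTSYN049
PLTSYN050
PLTSYN051
PLTSYN052
PLTSYN053
PLTSYN054
PLTSYN055
PLTSYN056
PLTSYN057
PLTSYN058
PLTSYN059
PLTSYN060
PLTSYN061
PLTSYN062
PLTSYN063
PLTSYN064
PLTSYN065
PLTSYN066
PLTSYN067
PLTSYN068
PLTSYN069
PLTSYN070
PLTSYN071
PLTSYN072
PLTSYN073
PLTSYN074
PLTSYN075
PLTSYN076
PLTSYN077
PLTSYN078
PLTSYN079
PLTSYN080
PLTSYN081
PLTSYN082
PLTSYN083
PLTSYN084
PLTSYN085
PLTSYN086
PLTSYN087
PLTSYN088
PLTSYN089
PLTSYN090
PLTSYN091
PLTSYN092
PLTSYN093
PLTSYN094
PLTSYN095
PLTSYN096
PLTSYN097
PLTSYN098
PLTSYN099
PLTSYN100
PLTSYN101
PLTSYN102
PLTSYN103
PLTSYN104
PLTSYN105
PLTSYN106
PLTSYN107
PLTSYN108
PLTSYN109
PLTSYN110
PLTSYN111
PLTSYN112
PLTSYN113
PLTSYN114
PLTSYN115
PLTSYN116
PLTSYN117
PLTSYN118
PLTSYN119
PLTSYN120
PLTSYN121
PLTSYN122
PLTSYN123
PLTSYN124
PLTSYN125
PLTSYN126
PLTSYN127
PLTSYN128
PLTSYN129
PLTSYN130
PLTSYN131
PLTSYN132
PLTSYN133
PLTSYN134
PLTSYN135
PLTSYN136
PLTSYN137
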