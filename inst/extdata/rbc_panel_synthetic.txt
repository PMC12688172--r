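# Synthetic stand-in erythroid (RBC) marker exclusion panel.
# A core of genuine marker gene symbols padded with synthetic symbols to
# the published cluster size; replace with the real cluster list for
# analyses of real data. One symbol per line.
HBB
HBA1
HBA2
HBD
HBG1
HBG2
HBM
HBQ1
ALAS2
SLC4A1
GYPA
GYPB
GYPC
GYPE
AHSP
CA1
CA2
EPB41
EPB42
SPTA1
SPTB
ANK1
RHAG
RHCE
RHD
KLF1
GATA1
TFRC
EPOR
SLC25A37
SNCA
BNIP3L
DMTN
TMOD1
SELENBP1
FECH
UROS
ALAD
CPOX
TSPO2
RBCSYN001
RBCSYN002
RBCSYN003
RBCSYN004
RBCSYN005
RBCSYN006
RBCSYN007
RBCSYN008
RBCSYN009
RBCSYN010
RBCSYN011
RBCSYN012
RBCSYN013
RBCSYN014
RBCSYN015
RBCSYN016
RBCSYN017
RBCSYN018
RBCSYN019
RBCSYN020
RBCSYN021
RBCSYN022
RBCSYN023
RBCSYN024
RBCSYN025
RBCSYN026
RBCSYN027
RBCSYN028
RBCSYN029
RBCSYN030
RBCSYN031
RBCSYN032
RBCSYN033
RBCSYN034
RBCSYN035
RBCSYN036
RBCSYN037
RBCSYN038
RBCSYN039
RBCSYN040
RBCSYN041
RBCSYN042
RBCSYN043
RBCSYN044
RBCSYN045
RBCSYN046
RBCSYN047
RBCSYN048
RBCSYN049
RBCSYN050
RBCSYN051
RBCSYN052
RBCSYN053
RBCSYN054
RBCSYN055
RBCSYN056
RBCSYN057
RBCSYN058
RBCSYN059
RBCSYN060
RBCSYN061
RBCSYN062
RBCSYN063
RBCSYN064
RBCSYN065
RBCSYN066
RBCSYN067
RBCSYN068
RBCSYN069
RBCSYN070
RBCSYN071
RBCSYN072
RBCSYN073
RBCSYN074
RBCSYN075
RBCSYN076
RBCSYN077
RBCSYN078
RBCSYN079
RBCSYN080
RBCSYN081
RBCSYN082
RBCSYN083
RBCSYN084
RBCSYN085
RBCSYN086
RBCSYN087
RBCSYN088
RBCSYN089
RBCSYN090
RBCSYN091
RBCSYN092
RBCSYN093
RBCSYN094
RBCSYN095
RBCSYN096
RBCSYN097
RBCSYN098
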