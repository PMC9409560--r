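# Synthetic stand-in list: 151 anti-epileptic drug target genes.
# Published symbols retained: the 17 risk-overlap genes and the 22
# co-expression-network genes; DTG* fillers are synthetic placeholders.
CACNA1A
CHRNA4
CHRNA7
GABRA1
GABRA2
GABRB2
GABRG2
GRIK1
GRIN1
GRIN2B
KCNQ2
KCNQ3
SCN1A
SCN2A
SCN3A
SCN8A
SCN9A
CACNA1C
CACNB2
CACNB4
CHRNB2
DNM1
EEF1A2
GABRA3
GABRA4
GABRB3
KCNA2
KCNC1
SCN4B
SOD1
STXBP1
SV2A
DTG001
DTG002
DTG003
DTG004
DTG005
DTG006
DTG007
DTG008
DTG009
DTG010
DTG011
DTG012
DTG013
DTG014
DTG015
DTG016
DTG017
DTG018
DTG019
DTG020
DTG021
DTG022
DTG023
DTG024
DTG025
DTG026
DTG027
DTG028
DTG029
DTG030
DTG031
DTG032
DTG033
DTG034
DTG035
DTG036
DTG037
DTG038
DTG039
DTG040
DTG041
DTG042
DTG043
DTG044
DTG045
DTG046
DTG047
DTG048
DTG049
DTG050
DTG051
DTG052
DTG053
DTG054
DTG055
DTG056
DTG057
DTG058
DTG059
DTG060
DTG061
DTG062
DTG063
DTG064
DTG065
DTG066
DTG067
DTG068
DTG069
DTG070
DTG071
DTG072
DTG073
DTG074
DTG075
DTG076
DTG077
DTG078
DTG079
DTG080
DTG081
DTG082
DTG083
DTG084
DTG085
DTG086
DTG087
DTG088
DTG089
DTG090
DTG091
DTG092
DTG093
DTG094
DTG095
DTG096
DTG097
DTG098
DTG099
DTG100
DTG101
DTG102
DTG103
DTG104
DTG105
DTG106
DTG107
DTG108
DTG109
DTG110
DTG111
DTG112
DTG113
DTG114
DTG115
DTG116
DTG117
DTG118
DTG119
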