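# Synthetic stand-in list: 102 rare-variant epilepsy risk genes.
# The 17 symbols shared with the drug-target list are real published gene
# symbols; RVG* fillers are synthetic placeholders.
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
RVG001
RVG002
RVG003
RVG004
RVG005
RVG006
RVG007
RVG008
RVG009
RVG010
RVG011
RVG012
RVG013
RVG014
RVG015
RVG016
RVG017
RVG018
RVG019
RVG020
RVG021
RVG022
RVG023
RVG024
RVG025
RVG026
RVG027
RVG028
RVG029
RVG030
RVG031
RVG032
RVG033
RVG034
RVG035
RVG036
RVG037
RVG038
RVG039
RVG040
RVG041
RVG042
RVG043
RVG044
RVG045
RVG046
RVG047
RVG048
RVG049
RVG050
RVG051
RVG052
RVG053
RVG054
RVG055
RVG056
RVG057
RVG058
RVG059
RVG060
RVG061
RVG062
RVG063
RVG064
RVG065
RVG066
RVG067
RVG068
RVG069
RVG070
RVG071
RVG072
RVG073
RVG074
RVG075
RVG076
RVG077
RVG078
RVG079
RVG080
RVG081
RVG082
RVG083
RVG084
RVG085
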