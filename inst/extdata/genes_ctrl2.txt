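# synthetic CTRL2 gene list (panel size 109)
CVD0001
CVD0002
CVD0003
CVD0004
CVD0005
CVD0006
CVD0007
CVD0008
CVD0009
CVD0010
CVD0011
CVD0012
CVD0013
CVD0014
CVD0015
CVD0016
CVD0017
CVD0018
CVD0019
CVD0020
CVD0021
CVD0022
CVD0023
CVD0024
CVD0025
CVD0026
CVD0027
CVD0028
CVD0029
CVD0030
CVD0031
CVD0032
CVD0033
CVD0034
CVD0035
CVD0036
CVD0037
CVD0038
CVD0039
CVD0040
CVD0041
CVD0042
CVD0043
CVD0044
CVD0045
CVD0046
CVD0047
CVD0048
CVD0049
CVD0050
CVD0051
CVD0052
CVD0053
CVD0054
CVD0055
CVD0056
CVD0057
CVD0058
CVD0059
CVD0060
CVD0061
CVD0062
CVD0063
CVD0064
CVD0065
CVD0066
CVD0067
CVD0068
CVD0069
CVD0070
CVD0071
CVD0072
CVD0073
CVD0074
CVD0075
CVD0076
CVD0077
CVD0078
CVD0079
CVD0080
CVD0081
CVD0082
CVD0083
CVD0084
CVD0085
CVD0086
CVD0087
CVD0088
CVD0089
CVD0090
CVD0091
CVD0092
CVD0093
CVD0094
CVD0095
CVD0096
CVD0097
CVD0098
CVD0099
CVD0100
CVD0101
CVD0102
CVD0103
CVD0104
CVD0105
CVD0106
CVD0107
CVD0108
CVD0109
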