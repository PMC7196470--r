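# synthetic CTRL3 gene list (panel size 223)
KID0001
KID0002
KID0003
KID0004
KID0005
KID0006
KID0007
KID0008
KID0009
KID0010
KID0011
KID0012
KID0013
KID0014
KID0015
KID0016
KID0017
KID0018
KID0019
KID0020
KID0021
KID0022
KID0023
KID0024
KID0025
KID0026
KID0027
KID0028
KID0029
KID0030
KID0031
KID0032
KID0033
KID0034
KID0035
KID0036
KID0037
KID0038
KID0039
KID0040
KID0041
KID0042
KID0043
KID0044
KID0045
KID0046
KID0047
KID0048
KID0049
KID0050
KID0051
KID0052
KID0053
KID0054
KID0055
KID0056
KID0057
KID0058
KID0059
KID0060
KID0061
KID0062
KID0063
KID0064
KID0065
KID0066
KID0067
KID0068
KID0069
KID0070
KID0071
KID0072
KID0073
KID0074
KID0075
KID0076
KID0077
KID0078
KID0079
KID0080
KID0081
KID0082
KID0083
KID0084
KID0085
KID0086
KID0087
KID0088
KID0089
KID0090
KID0091
KID0092
KID0093
KID0094
KID0095
KID0096
KID0097
KID0098
KID0099
KID0100
KID0101
KID0102
KID0103
KID0104
KID0105
KID0106
KID0107
KID0108
KID0109
KID0110
KID0111
KID0112
KID0113
KID0114
KID0115
KID0116
KID0117
KID0118
KID0119
KID0120
KID0121
KID0122
KID0123
KID0124
KID0125
KID0126
KID0127
KID0128
KID0129
KID0130
KID0131
KID0132
KID0133
KID0134
KID0135
KID0136
KID0137
KID0138
KID0139
KID0140
KID0141
KID0142
KID0143
KID0144
KID0145
KID0146
KID0147
KID0148
KID0149
KID0150
KID0151
KID0152
KID0153
KID0154
KID0155
KID0156
KID0157
KID0158
KID0159
KID0160
KID0161
KID0162
KID0163
KID0164
KID0165
KID0166
KID0167
KID0168
KID0169
KID0170
KID0171
KID0172
KID0173
KID0174
KID0175
KID0176
KID0177
KID0178
KID0179
KID0180
KID0181
KID0182
KID0183
KID0184
KID0185
KID0186
KID0187
KID0188
KID0189
KID0190
KID0191
KID0192
KID0193
KID0194
KID0195
KID0196
KID0197
KID0198
KID0199
KID0200
KID0201
KID0202
KID0203
KID0204
KID0205
KID0206
KID0207
KID0208
KID0209
KID0210
KID0211
KID0212
KID0213
KID0214
KID0215
KID0216
KID0217
KID0218
KID0219
KID0220
KID0221
KID0222
KID0223
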