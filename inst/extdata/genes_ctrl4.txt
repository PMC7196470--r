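# synthetic CTRL4 gene list (panel size 297)
HEM0001
HEM0002
HEM0003
HEM0004
HEM0005
HEM0006
HEM0007
HEM0008
HEM0009
HEM0010
HEM0011
HEM0012
HEM0013
HEM0014
HEM0015
HEM0016
HEM0017
HEM0018
HEM0019
HEM0020
HEM0021
HEM0022
HEM0023
HEM0024
HEM0025
HEM0026
HEM0027
HEM0028
HEM0029
HEM0030
HEM0031
HEM0032
HEM0033
HEM0034
HEM0035
HEM0036
HEM0037
HEM0038
HEM0039
HEM0040
HEM0041
HEM0042
HEM0043
HEM0044
HEM0045
HEM0046
HEM0047
HEM0048
HEM0049
HEM0050
HEM0051
HEM0052
HEM0053
HEM0054
HEM0055
HEM0056
HEM0057
HEM0058
HEM0059
HEM0060
HEM0061
HEM0062
HEM0063
HEM0064
HEM0065
HEM0066
HEM0067
HEM0068
HEM0069
HEM0070
HEM0071
HEM0072
HEM0073
HEM0074
HEM0075
HEM0076
HEM0077
HEM0078
HEM0079
HEM0080
HEM0081
HEM0082
HEM0083
HEM0084
HEM0085
HEM0086
HEM0087
HEM0088
HEM0089
HEM0090
HEM0091
HEM0092
HEM0093
HEM0094
HEM0095
HEM0096
HEM0097
HEM0098
HEM0099
HEM0100
HEM0101
HEM0102
HEM0103
HEM0104
HEM0105
HEM0106
HEM0107
HEM0108
HEM0109
HEM0110
HEM0111
HEM0112
HEM0113
HEM0114
HEM0115
HEM0116
HEM0117
HEM0118
HEM0119
HEM0120
HEM0121
HEM0122
HEM0123
HEM0124
HEM0125
HEM0126
HEM0127
HEM0128
HEM0129
HEM0130
HEM0131
HEM0132
HEM0133
HEM0134
HEM0135
HEM0136
HEM0137
HEM0138
HEM0139
HEM0140
HEM0141
HEM0142
HEM0143
HEM0144
HEM0145
HEM0146
HEM0147
HEM0148
HEM0149
HEM0150
HEM0151
HEM0152
HEM0153
HEM0154
HEM0155
HEM0156
HEM0157
HEM0158
HEM0159
HEM0160
HEM0161
HEM0162
HEM0163
HEM0164
HEM0165
HEM0166
HEM0167
HEM0168
HEM0169
HEM0170
HEM0171
HEM0172
HEM0173
HEM0174
HEM0175
HEM0176
HEM0177
HEM0178
HEM0179
HEM0180
HEM0181
HEM0182
HEM0183
HEM0184
HEM0185
HEM0186
HEM0187
HEM0188
HEM0189
HEM0190
HEM0191
HEM0192
HEM0193
HEM0194
HEM0195
HEM0196
HEM0197
HEM0198
HEM0199
HEM0200
HEM0201
HEM0202
HEM0203
HEM0204
HEM0205
HEM0206
HEM0207
HEM0208
HEM0209
HEM0210
HEM0211
HEM0212
HEM0213
HEM0214
HEM0215
HEM0216
HEM0217
HEM0218
HEM0219
HEM0220
HEM0221
HEM0222
HEM0223
HEM0224
HEM0225
HEM0226
HEM0227
HEM0228
HEM0229
HEM0230
HEM0231
HEM0232
HEM0233
HEM0234
HEM0235
HEM0236
HEM0237
HEM0238
HEM0239
HEM0240
HEM0241
HEM0242
HEM0243
HEM0244
HEM0245
HEM0246
HEM0247
HEM0248
HEM0249
HEM0250
HEM0251
HEM0252
HEM0253
HEM0254
HEM0255
HEM0256
HEM0257
HEM0258
HEM0259
HEM0260
HEM0261
HEM0262
HEM0263
HEM0264
HEM0265
HEM0266
HEM0267
HEM0268
HEM0269
HEM0270
HEM0271
HEM0272
HEM0273
HEM0274
HEM0275
HEM0276
HEM0277
HEM0278
HEM0279
HEM0280
HEM0281
HEM0282
HEM0283
HEM0284
HEM0285
HEM0286
HEM0287
HEM0288
HEM0289
HEM0290
HEM0291
HEM0292
HEM0293
HEM0294
HEM0295
HEM0296
HEM0297
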