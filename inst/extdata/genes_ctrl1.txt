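# synthetic CTRL1 gene list (panel size 360)
IMM0001
IMM0002
IMM0003
IMM0004
IMM0005
IMM0006
IMM0007
IMM0008
IMM0009
IMM0010
IMM0011
IMM0012
IMM0013
IMM0014
IMM0015
IMM0016
IMM0017
IMM0018
IMM0019
IMM0020
IMM0021
IMM0022
IMM0023
IMM0024
IMM0025
IMM0026
IMM0027
IMM0028
IMM0029
IMM0030
IMM0031
IMM0032
IMM0033
IMM0034
IMM0035
IMM0036
IMM0037
IMM0038
IMM0039
IMM0040
IMM0041
IMM0042
IMM0043
IMM0044
IMM0045
IMM0046
IMM0047
IMM0048
IMM0049
IMM0050
IMM0051
IMM0052
IMM0053
IMM0054
IMM0055
IMM0056
IMM0057
IMM0058
IMM0059
IMM0060
IMM0061
IMM0062
IMM0063
IMM0064
IMM0065
IMM0066
IMM0067
IMM0068
IMM0069
IMM0070
IMM0071
IMM0072
IMM0073
IMM0074
IMM0075
IMM0076
IMM0077
IMM0078
IMM0079
IMM0080
IMM0081
IMM0082
IMM0083
IMM0084
IMM0085
IMM0086
IMM0087
IMM0088
IMM0089
IMM0090
IMM0091
IMM0092
IMM0093
IMM0094
IMM0095
IMM0096
IMM0097
IMM0098
IMM0099
IMM0100
IMM0101
IMM0102
IMM0103
IMM0104
IMM0105
IMM0106
IMM0107
IMM0108
IMM0109
IMM0110
IMM0111
IMM0112
IMM0113
IMM0114
IMM0115
IMM0116
IMM0117
IMM0118
IMM0119
IMM0120
IMM0121
IMM0122
IMM0123
IMM0124
IMM0125
IMM0126
IMM0127
IMM0128
IMM0129
IMM0130
IMM0131
IMM0132
IMM0133
IMM0134
IMM0135
IMM0136
IMM0137
IMM0138
IMM0139
IMM0140
IMM0141
IMM0142
IMM0143
IMM0144
IMM0145
IMM0146
IMM0147
IMM0148
IMM0149
IMM0150
IMM0151
IMM0152
IMM0153
IMM0154
IMM0155
IMM0156
IMM0157
IMM0158
IMM0159
IMM0160
IMM0161
IMM0162
IMM0163
IMM0164
IMM0165
IMM0166
IMM0167
IMM0168
IMM0169
IMM0170
IMM0171
IMM0172
IMM0173
IMM0174
IMM0175
IMM0176
IMM0177
IMM0178
IMM0179
IMM0180
IMM0181
IMM0182
IMM0183
IMM0184
IMM0185
IMM0186
IMM0187
IMM0188
IMM0189
IMM0190
IMM0191
IMM0192
IMM0193
IMM0194
IMM0195
IMM0196
IMM0197
IMM0198
IMM0199
IMM0200
IMM0201
IMM0202
IMM0203
IMM0204
IMM0205
IMM0206
IMM0207
IMM0208
IMM0209
IMM0210
IMM0211
IMM0212
IMM0213
IMM0214
IMM0215
IMM0216
IMM0217
IMM0218
IMM0219
IMM0220
IMM0221
IMM0222
IMM0223
IMM0224
IMM0225
IMM0226
IMM0227
IMM0228
IMM0229
IMM0230
IMM0231
IMM0232
IMM0233
IMM0234
IMM0235
IMM0236
IMM0237
IMM0238
IMM0239
IMM0240
IMM0241
IMM0242
IMM0243
IMM0244
IMM0245
IMM0246
IMM0247
IMM0248
IMM0249
IMM0250
IMM0251
IMM0252
IMM0253
IMM0254
IMM0255
IMM0256
IMM0257
IMM0258
IMM0259
IMM0260
IMM0261
IMM0262
IMM0263
IMM0264
IMM0265
IMM0266
IMM0267
IMM0268
IMM0269
IMM0270
IMM0271
IMM0272
IMM0273
IMM0274
IMM0275
IMM0276
IMM0277
IMM0278
IMM0279
IMM0280
IMM0281
IMM0282
IMM0283
IMM0284
IMM0285
IMM0286
IMM0287
IMM0288
IMM0289
IMM0290
IMM0291
IMM0292
IMM0293
IMM0294
IMM0295
IMM0296
IMM0297
IMM0298
IMM0299
IMM0300
IMM0301
IMM0302
IMM0303
IMM0304
IMM0305
IMM0306
IMM0307
IMM0308
IMM0309
IMM0310
IMM0311
IMM0312
IMM0313
IMM0314
IMM0315
IMM0316
IMM0317
IMM0318
IMM0319
IMM0320
IMM0321
IMM0322
IMM0323
IMM0324
IMM0325
IMM0326
IMM0327
IMM0328
IMM0329
IMM0330
IMM0331
IMM0332
IMM0333
IMM0334
IMM0335
IMM0336
IMM0337
IMM0338
IMM0339
IMM0340
IMM0341
IMM0342
IMM0343
IMM0344
IMM0345
IMM0346
IMM0347
IMM0348
IMM0349
IMM0350
IMM0351
IMM0352
IMM0353
IMM0354
IMM0355
IMM0356
IMM0357
IMM0358
IMM0359
IMM0360
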