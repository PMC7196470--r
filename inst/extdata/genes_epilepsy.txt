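# synthetic EPILEPSY gene list (panel size 422)
EPI0002
EPI0003
EPI0004
EPI0005
EPI0006
EPI0007
EPI0008
EPI0009
EPI0010
EPI0011
EPI0012
EPI0013
EPI0014
EPI0015
EPI0016
EPI0017
EPI0018
EPI0019
EPI0020
EPI0021
EPI0022
EPI0023
EPI0024
EPI0025
EPI0026
EPI0027
EPI0028
EPI0029
EPI0030
EPI0031
EPI0032
EPI0033
EPI0034
EPI0035
EPI0036
EPI0037
EPI0038
EPI0039
EPI0040
EPI0041
EPI0042
EPI0043
EPI0044
EPI0045
EPI0046
EPI0047
EPI0048
EPI0049
EPI0050
EPI0051
EPI0052
EPI0053
EPI0054
EPI0055
EPI0056
EPI0057
EPI0058
EPI0059
EPI0060
EPI0061
EPI0062
EPI0063
EPI0064
EPI0065
EPI0066
EPI0067
EPI0068
EPI0069
EPI0070
EPI0071
EPI0072
EPI0073
EPI0074
EPI0075
EPI0076
EPI0077
EPI0078
EPI0079
EPI0080
EPI0081
EPI0082
EPI0083
EPI0084
EPI0085
EPI0086
EPI0087
EPI0088
EPI0089
EPI0090
EPI0091
EPI0092
EPI0093
EPI0094
EPI0095
EPI0096
EPI0097
EPI0098
EPI0099
EPI0100
EPI0101
EPI0102
EPI0103
EPI0104
EPI0105
EPI0106
EPI0107
EPI0108
EPI0109
EPI0110
EPI0111
EPI0112
EPI0113
EPI0114
EPI0115
EPI0116
EPI0117
EPI0118
EPI0119
EPI0120
EPI0121
EPI0122
EPI0123
EPI0124
EPI0125
EPI0126
EPI0127
EPI0128
EPI0129
EPI0130
EPI0131
EPI0132
EPI0133
EPI0134
EPI0135
EPI0136
EPI0137
EPI0138
EPI0139
EPI0140
EPI0141
EPI0142
EPI0143
EPI0144
EPI0145
EPI0146
EPI0147
EPI0148
EPI0149
EPI0150
EPI0151
EPI0152
EPI0153
EPI0154
EPI0155
EPI0156
EPI0157
EPI0158
EPI0159
EPI0160
EPI0161
EPI0162
EPI0163
EPI0164
EPI0165
EPI0166
EPI0167
EPI0168
EPI0169
EPI0170
EPI0171
EPI0172
EPI0173
EPI0174
EPI0175
EPI0176
EPI0177
EPI0178
EPI0179
EPI0180
EPI0181
EPI0182
EPI0183
EPI0184
EPI0185
EPI0186
EPI0187
EPI0188
EPI0189
EPI0190
EPI0191
EPI0192
EPI0193
EPI0194
EPI0195
EPI0196
EPI0197
EPI0198
EPI0199
EPI0200
EPI0201
EPI0202
EPI0203
EPI0204
EPI0205
EPI0206
EPI0207
EPI0208
EPI0209
EPI0210
EPI0211
EPI0212
EPI0213
EPI0214
EPI0215
EPI0216
EPI0217
EPI0218
EPI0219
EPI0220
EPI0221
EPI0222
EPI0223
EPI0224
EPI0225
EPI0226
EPI0227
EPI0228
EPI0229
EPI0230
EPI0231
EPI0232
EPI0233
EPI0234
EPI0235
EPI0236
EPI0237
EPI0238
EPI0239
EPI0240
EPI0241
EPI0242
EPI0243
EPI0244
EPI0245
EPI0246
EPI0247
EPI0248
EPI0249
EPI0250
EPI0251
EPI0252
EPI0253
EPI0254
EPI0255
EPI0256
EPI0257
EPI0258
EPI0259
EPI0260
EPI0261
EPI0262
EPI0263
EPI0264
EPI0265
EPI0266
EPI0267
EPI0268
EPI0269
EPI0270
EPI0271
EPI0272
EPI0273
EPI0274
EPI0275
EPI0276
EPI0277
EPI0278
EPI0279
EPI0280
EPI0281
EPI0282
EPI0283
EPI0284
EPI0285
EPI0286
EPI0287
EPI0288
EPI0289
EPI0290
EPI0291
EPI0292
EPI0293
EPI0294
EPI0295
EPI0296
EPI0297
EPI0298
EPI0299
EPI0300
EPI0301
EPI0302
EPI0303
EPI0304
EPI0305
EPI0306
EPI0307
EPI0308
EPI0309
EPI0310
EPI0311
EPI0312
EPI0313
EPI0314
EPI0315
EPI0316
EPI0317
EPI0318
EPI0319
EPI0320
EPI0321
EPI0322
EPI0323
EPI0324
EPI0325
EPI0326
EPI0327
EPI0328
EPI0329
EPI0330
EPI0331
EPI0332
EPI0333
EPI0334
EPI0335
EPI0336
EPI0337
EPI0338
EPI0339
EPI0340
EPI0341
EPI0342
EPI0343
EPI0344
EPI0345
EPI0346
EPI0347
EPI0348
EPI0349
EPI0350
EPI0351
EPI0352
EPI0353
EPI0354
EPI0355
EPI0356
EPI0357
EPI0358
EPI0359
EPI0360
EPI0361
EPI0362
EPI0363
EPI0364
EPI0365
EPI0366
EPI0367
EPI0368
EPI0369
EPI0370
EPI0371
EPI0372
EPI0373
EPI0374
EPI0375
EPI0376
EPI0377
EPI0378
EPI0379
EPI0380
EPI0381
EPI0382
EPI0383
EPI0384
EPI0385
EPI0386
EPI0387
EPI0388
EPI0389
EPI0390
EPI0391
EPI0392
EPI0393
EPI0394
EPI0395
EPI0396
EPI0397
EPI0398
EPI0399
EPI0400
EPI0401
EPI0402
EPI0403
EPI0404
EPI0405
EPI0406
EPI0407
EPI0408
EPI0409
EPI0410
EPI0411
EPI0412
EPI0413
EPI0414
EPI0415
EPI0416
EPI0417
EPI0418
EPI0419
EPI0420
EPI0421
EPI0422
SCN1A
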