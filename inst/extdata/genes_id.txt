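# synthetic ID gene list (panel size 659)
IDG0001
IDG0002
IDG0003
IDG0004
IDG0005
IDG0006
IDG0007
IDG0008
IDG0009
IDG0010
IDG0011
IDG0012
IDG0013
IDG0014
IDG0015
IDG0016
IDG0017
IDG0018
IDG0019
IDG0020
IDG0021
IDG0022
IDG0023
IDG0024
IDG0025
IDG0026
IDG0027
IDG0028
IDG0029
IDG0030
IDG0031
IDG0032
IDG0033
IDG0034
IDG0035
IDG0036
IDG0037
IDG0038
IDG0039
IDG0040
IDG0041
IDG0042
IDG0043
IDG0044
IDG0045
IDG0046
IDG0047
IDG0048
IDG0049
IDG0050
IDG0051
IDG0052
IDG0053
IDG0054
IDG0055
IDG0056
IDG0057
IDG0058
IDG0059
IDG0060
IDG0061
IDG0062
IDG0063
IDG0064
IDG0065
IDG0066
IDG0067
IDG0068
IDG0069
IDG0070
IDG0071
IDG0072
IDG0073
IDG0074
IDG0075
IDG0076
IDG0077
IDG0078
IDG0079
IDG0080
IDG0081
IDG0082
IDG0083
IDG0084
IDG0085
IDG0086
IDG0087
IDG0088
IDG0089
IDG0090
IDG0091
IDG0092
IDG0093
IDG0094
IDG0095
IDG0096
IDG0097
IDG0098
IDG0099
IDG0100
IDG0101
IDG0102
IDG0103
IDG0104
IDG0105
IDG0106
IDG0107
IDG0108
IDG0109
IDG0110
IDG0111
IDG0112
IDG0113
IDG0114
IDG0115
IDG0116
IDG0117
IDG0118
IDG0119
IDG0120
IDG0121
IDG0122
IDG0123
IDG0124
IDG0125
IDG0126
IDG0127
IDG0128
IDG0129
IDG0130
IDG0131
IDG0132
IDG0133
IDG0134
IDG0135
IDG0136
IDG0137
IDG0138
IDG0139
IDG0140
IDG0141
IDG0142
IDG0143
IDG0144
IDG0145
IDG0146
IDG0147
IDG0148
IDG0149
IDG0150
IDG0151
IDG0152
IDG0153
IDG0154
IDG0155
IDG0156
IDG0157
IDG0158
IDG0159
IDG0160
IDG0161
IDG0162
IDG0163
IDG0164
IDG0165
IDG0166
IDG0167
IDG0168
IDG0169
IDG0170
IDG0171
IDG0172
IDG0173
IDG0174
IDG0175
IDG0176
IDG0177
IDG0178
IDG0179
IDG0180
IDG0181
IDG0182
IDG0183
IDG0184
IDG0185
IDG0186
IDG0187
IDG0188
IDG0189
IDG0190
IDG0191
IDG0192
IDG0193
IDG0194
IDG0195
IDG0196
IDG0197
IDG0198
IDG0199
IDG0200
IDG0201
IDG0202
IDG0203
IDG0204
IDG0205
IDG0206
IDG0207
IDG0208
IDG0209
IDG0210
IDG0211
IDG0212
IDG0213
IDG0214
IDG0215
IDG0216
IDG0217
IDG0218
IDG0219
IDG0220
IDG0221
IDG0222
IDG0223
IDG0224
IDG0225
IDG0226
IDG0227
IDG0228
IDG0229
IDG0230
IDG0231
IDG0232
IDG0233
IDG0234
IDG0235
IDG0236
IDG0237
IDG0238
IDG0239
IDG0240
IDG0241
IDG0242
IDG0243
IDG0244
IDG0245
IDG0246
IDG0247
IDG0248
IDG0249
IDG0250
IDG0251
IDG0252
IDG0253
IDG0254
IDG0255
IDG0256
IDG0257
IDG0258
IDG0259
IDG0260
IDG0261
IDG0262
IDG0263
IDG0264
IDG0265
IDG0266
IDG0267
IDG0268
IDG0269
IDG0270
IDG0271
IDG0272
IDG0273
IDG0274
IDG0275
IDG0276
IDG0277
IDG0278
IDG0279
IDG0280
IDG0281
IDG0282
IDG0283
IDG0284
IDG0285
IDG0286
IDG0287
IDG0288
IDG0289
IDG0290
IDG0291
IDG0292
IDG0293
IDG0294
IDG0295
IDG0296
IDG0297
IDG0298
IDG0299
IDG0300
IDG0301
IDG0302
IDG0303
IDG0304
IDG0305
IDG0306
IDG0307
IDG0308
IDG0309
IDG0310
IDG0311
IDG0312
IDG0313
IDG0314
IDG0315
IDG0316
IDG0317
IDG0318
IDG0319
IDG0320
IDG0321
IDG0322
IDG0323
IDG0324
IDG0325
IDG0326
IDG0327
IDG0328
IDG0329
IDG0330
IDG0331
IDG0332
IDG0333
IDG0334
IDG0335
IDG0336
IDG0337
IDG0338
IDG0339
IDG0340
IDG0341
IDG0342
IDG0343
IDG0344
IDG0345
IDG0346
IDG0347
IDG0348
IDG0349
IDG0350
IDG0351
IDG0352
IDG0353
IDG0354
IDG0355
IDG0356
IDG0357
IDG0358
IDG0359
IDG0360
IDG0361
IDG0362
IDG0363
IDG0364
IDG0365
IDG0366
IDG0367
IDG0368
IDG0369
IDG0370
IDG0371
IDG0372
IDG0373
IDG0374
IDG0375
IDG0376
IDG0377
IDG0378
IDG0379
IDG0380
IDG0381
IDG0382
IDG0383
IDG0384
IDG0385
IDG0386
IDG0387
IDG0388
IDG0389
IDG0390
IDG0391
IDG0392
IDG0393
IDG0394
IDG0395
IDG0396
IDG0397
IDG0398
IDG0399
IDG0400
IDG0401
IDG0402
IDG0403
IDG0404
IDG0405
IDG0406
IDG0407
IDG0408
IDG0409
IDG0410
IDG0411
IDG0412
IDG0413
IDG0414
IDG0415
IDG0416
IDG0417
IDG0418
IDG0419
IDG0420
IDG0421
IDG0422
IDG0423
IDG0424
IDG0425
IDG0426
IDG0427
IDG0428
IDG0429
IDG0430
IDG0431
IDG0432
IDG0433
IDG0434
IDG0435
IDG0436
IDG0437
IDG0438
IDG0439
IDG0440
IDG0441
IDG0442
IDG0443
IDG0444
IDG0445
IDG0446
IDG0447
IDG0448
IDG0449
IDG0450
IDG0451
IDG0452
IDG0453
IDG0454
IDG0455
IDG0456
IDG0457
IDG0458
IDG0459
IDG0460
IDG0461
IDG0462
IDG0463
IDG0464
IDG0465
IDG0466
IDG0467
IDG0468
IDG0469
IDG0470
IDG0471
IDG0472
IDG0473
IDG0474
IDG0475
IDG0476
IDG0477
IDG0478
IDG0479
IDG0480
IDG0481
IDG0482
IDG0483
IDG0484
IDG0485
IDG0486
IDG0487
IDG0488
IDG0489
IDG0490
IDG0491
IDG0492
IDG0493
IDG0494
IDG0495
IDG0496
IDG0497
IDG0498
IDG0499
IDG0500
IDG0501
IDG0502
IDG0503
IDG0504
IDG0505
IDG0506
IDG0507
IDG0508
IDG0509
IDG0510
IDG0511
IDG0512
IDG0513
IDG0514
IDG0515
IDG0516
IDG0517
IDG0518
IDG0519
IDG0520
IDG0521
IDG0522
IDG0523
IDG0524
IDG0525
IDG0526
IDG0527
IDG0528
IDG0529
IDG0530
IDG0531
IDG0532
IDG0533
IDG0534
IDG0535
IDG0536
IDG0537
IDG0538
IDG0539
IDG0540
IDG0541
IDG0542
IDG0543
IDG0544
IDG0545
IDG0546
IDG0547
IDG0548
IDG0549
IDG0550
IDG0551
IDG0552
IDG0553
IDG0554
IDG0555
IDG0556
IDG0557
IDG0558
IDG0559
IDG0560
IDG0561
IDG0562
IDG0563
IDG0564
IDG0565
IDG0566
IDG0567
IDG0568
IDG0569
IDG0570
IDG0571
IDG0572
IDG0573
IDG0574
IDG0575
IDG0576
IDG0577
IDG0578
IDG0579
IDG0580
IDG0581
IDG0582
IDG0583
IDG0584
IDG0585
IDG0586
IDG0587
IDG0588
IDG0589
IDG0590
IDG0591
IDG0592
IDG0593
IDG0594
IDG0595
IDG0596
IDG0597
IDG0598
IDG0599
IDG0600
IDG0601
IDG0602
IDG0603
IDG0604
IDG0605
IDG0606
IDG0607
IDG0608
IDG0609
IDG0610
IDG0611
IDG0612
IDG0613
IDG0614
IDG0615
IDG0616
IDG0617
IDG0618
IDG0619
IDG0620
IDG0621
IDG0622
IDG0623
IDG0624
IDG0625
IDG0626
IDG0627
IDG0628
IDG0629
IDG0630
IDG0631
IDG0632
IDG0633
IDG0634
IDG0635
IDG0636
IDG0637
IDG0638
IDG0639
IDG0640
IDG0641
IDG0642
IDG0643
IDG0644
IDG0645
IDG0646
IDG0647
IDG0648
IDG0649
IDG0650
IDG0651
IDG0652
IDG0653
IDG0654
IDG0655
IDG0656
IDG0657
IDG0658
IDG0659
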