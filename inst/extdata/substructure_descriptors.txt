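PCFP0000
PCFP0001
PCFP0002
PCFP0003
PCFP0004
PCFP0005
PCFP0006
PCFP0007
PCFP0008
PCFP0009
PCFP0010
PCFP0011
PCFP0012
PCFP0013
PCFP0014
PCFP0015
PCFP0016
PCFP0017
PCFP0018
PCFP0019
PCFP0020
PCFP0021
PCFP0022
PCFP0023
PCFP0024
PCFP0025
PCFP0026
PCFP0027
PCFP0028
PCFP0029
PCFP0030
PCFP0031
PCFP0032
PCFP0033
PCFP0034
PCFP0035
PCFP0036
PCFP0037
PCFP0038
PCFP0039
PCFP0040
PCFP0041
PCFP0042
PCFP0043
PCFP0044
PCFP0045
PCFP0046
PCFP0047
PCFP0048
PCFP0049
PCFP0050
PCFP0051
PCFP0052
PCFP0053
PCFP0054
PCFP0055
PCFP0056
PCFP0057
PCFP0058
PCFP0059
PCFP0060
PCFP0061
PCFP0062
PCFP0063
PCFP0064
PCFP0065
PCFP0066
PCFP0067
PCFP0068
PCFP0069
PCFP0070
PCFP0071
PCFP0072
PCFP0073
PCFP0074
PCFP0075
PCFP0076
PCFP0077
PCFP0078
PCFP0079
PCFP0080
PCFP0081
PCFP0082
PCFP0083
PCFP0084
PCFP0085
PCFP0086
PCFP0087
PCFP0088
PCFP0089
PCFP0090
PCFP0091
PCFP0092
PCFP0093
PCFP0094
PCFP0095
PCFP0096
PCFP0097
PCFP0098
PCFP0099
PCFP0100
PCFP0101
PCFP0102
PCFP0103
PCFP0104
PCFP0105
PCFP0106
PCFP0107
PCFP0108
PCFP0109
PCFP0110
PCFP0111
PCFP0112
PCFP0113
PCFP0114
PCFP0115
PCFP0116
PCFP0117
PCFP0118
PCFP0119
PCFP0120
PCFP0121
PCFP0122
PCFP0123
PCFP0124
PCFP0125
PCFP0126
PCFP0127
PCFP0128
PCFP0129
PCFP0130
PCFP0131
PCFP0132
PCFP0133
PCFP0134
PCFP0135
PCFP0136
PCFP0137
PCFP0138
PCFP0139
PCFP0140
PCFP0141
PCFP0142
PCFP0143
PCFP0144
PCFP0145
PCFP0146
PCFP0147
PCFP0148
PCFP0149
PCFP0150
PCFP0151
PCFP0152
PCFP0153
PCFP0154
PCFP0155
PCFP0156
PCFP0157
PCFP0158
PCFP0159
PCFP0160
PCFP0161
PCFP0162
PCFP0163
PCFP0164
PCFP0165
PCFP0166
PCFP0167
PCFP0168
PCFP0169
PCFP0170
PCFP0171
PCFP0172
PCFP0173
PCFP0174
PCFP0175
PCFP0176
PCFP0177
PCFP0178
PCFP0179
PCFP0180
PCFP0181
PCFP0182
PCFP0183
PCFP0184
PCFP0185
PCFP0186
PCFP0187
PCFP0188
PCFP0189
PCFP0190
PCFP0191
PCFP0192
PCFP0193
PCFP0194
PCFP0195
PCFP0196
PCFP0197
PCFP0198
PCFP0199
PCFP0200
PCFP0201
PCFP0202
PCFP0203
PCFP0204
PCFP0205
PCFP0206
PCFP0207
PCFP0208
PCFP0209
PCFP0210
PCFP0211
PCFP0212
PCFP0213
PCFP0214
PCFP0215
PCFP0216
PCFP0217
PCFP0218
PCFP0219
PCFP0220
PCFP0221
PCFP0222
PCFP0223
PCFP0224
PCFP0225
PCFP0226
PCFP0227
PCFP0228
PCFP0229
PCFP0230
PCFP0231
PCFP0232
PCFP0233
PCFP0234
PCFP0235
PCFP0236
PCFP0237
PCFP0238
PCFP0239
PCFP0240
PCFP0241
PCFP0242
PCFP0243
PCFP0244
PCFP0245
PCFP0246
PCFP0247
PCFP0248
PCFP0249
PCFP0250
PCFP0251
PCFP0252
PCFP0253
PCFP0254
PCFP0255
PCFP0256
PCFP0257
PCFP0258
PCFP0259
PCFP0260
PCFP0261
PCFP0262
PCFP0263
PCFP0264
PCFP0265
PCFP0266
PCFP0267
PCFP0268
PCFP0269
PCFP0270
PCFP0271
PCFP0272
PCFP0273
PCFP0274
PCFP0275
PCFP0276
PCFP0277
PCFP0278
PCFP0279
PCFP0280
PCFP0281
PCFP0282
PCFP0283
PCFP0284
PCFP0285
PCFP0286
PCFP0287
PCFP0288
PCFP0289
PCFP0290
PCFP0291
PCFP0292
PCFP0293
PCFP0294
PCFP0295
PCFP0296
PCFP0297
PCFP0298
PCFP0299
PCFP0300
PCFP0301
PCFP0302
PCFP0303
PCFP0304
PCFP0305
PCFP0306
PCFP0307
PCFP0308
PCFP0309
PCFP0310
PCFP0311
PCFP0312
PCFP0313
PCFP0314
PCFP0315
PCFP0316
PCFP0317
PCFP0318
PCFP0319
PCFP0320
PCFP0321
PCFP0322
PCFP0323
PCFP0324
PCFP0325
PCFP0326
PCFP0327
PCFP0328
PCFP0329
PCFP0330
PCFP0331
PCFP0332
PCFP0333
PCFP0334
PCFP0335
PCFP0336
PCFP0337
PCFP0338
PCFP0339
PCFP0340
PCFP0341
PCFP0342
PCFP0343
PCFP0344
PCFP0345
PCFP0346
PCFP0347
PCFP0348
PCFP0349
PCFP0350
PCFP0351
PCFP0352
PCFP0353
PCFP0354
PCFP0355
PCFP0356
PCFP0357
PCFP0358
PCFP0359
PCFP0360
PCFP0361
PCFP0362
PCFP0363
PCFP0364
PCFP0365
PCFP0366
PCFP0367
PCFP0368
PCFP0369
PCFP0370
PCFP0371
PCFP0372
PCFP0373
PCFP0374
PCFP0375
PCFP0376
PCFP0377
PCFP0378
PCFP0379
PCFP0380
PCFP0381
PCFP0382
PCFP0383
PCFP0384
PCFP0385
PCFP0386
PCFP0387
PCFP0388
PCFP0389
PCFP0390
PCFP0391
PCFP0392
PCFP0393
PCFP0394
PCFP0395
PCFP0396
PCFP0397
PCFP0398
PCFP0399
PCFP0400
PCFP0401
PCFP0402
PCFP0403
PCFP0404
PCFP0405
PCFP0406
PCFP0407
PCFP0408
PCFP0409
PCFP0410
PCFP0411
PCFP0412
PCFP0413
PCFP0414
PCFP0415
PCFP0416
PCFP0417
PCFP0418
PCFP0419
PCFP0420
PCFP0421
PCFP0422
PCFP0423
PCFP0424
PCFP0425
PCFP0426
PCFP0427
PCFP0428
PCFP0429
PCFP0430
PCFP0431
PCFP0432
PCFP0433
PCFP0434
PCFP0435
PCFP0436
PCFP0437
PCFP0438
PCFP0439
PCFP0440
PCFP0441
PCFP0442
PCFP0443
PCFP0444
PCFP0445
PCFP0446
PCFP0447
PCFP0448
PCFP0449
PCFP0450
PCFP0451
PCFP0452
PCFP0453
PCFP0454
PCFP0455
PCFP0456
PCFP0457
PCFP0458
PCFP0459
PCFP0460
PCFP0461
PCFP0462
PCFP0463
PCFP0464
PCFP0465
PCFP0466
PCFP0467
PCFP0468
PCFP0469
PCFP0470
PCFP0471
PCFP0472
PCFP0473
PCFP0474
PCFP0475
PCFP0476
PCFP0477
PCFP0478
PCFP0479
PCFP0480
PCFP0481
PCFP0482
PCFP0483
PCFP0484
PCFP0485
PCFP0486
PCFP0487
PCFP0488
PCFP0489
PCFP0490
PCFP0491
PCFP0492
PCFP0493
PCFP0494
PCFP0495
PCFP0496
PCFP0497
PCFP0498
PCFP0499
PCFP0500
PCFP0501
PCFP0502
PCFP0503
PCFP0504
PCFP0505
PCFP0506
PCFP0507
PCFP0508
PCFP0509
PCFP0510
PCFP0511
PCFP0512
PCFP0513
PCFP0514
PCFP0515
PCFP0516
PCFP0517
PCFP0518
PCFP0519
PCFP0520
PCFP0521
PCFP0522
PCFP0523
PCFP0524
PCFP0525
PCFP0526
PCFP0527
PCFP0528
PCFP0529
PCFP0530
PCFP0531
PCFP0532
PCFP0533
PCFP0534
PCFP0535
PCFP0536
PCFP0537
PCFP0538
PCFP0539
PCFP0540
PCFP0541
PCFP0542
PCFP0543
PCFP0544
PCFP0545
PCFP0546
PCFP0547
PCFP0548
PCFP0549
PCFP0550
PCFP0551
PCFP0552
PCFP0553
PCFP0554
PCFP0555
PCFP0556
PCFP0557
PCFP0558
PCFP0559
PCFP0560
PCFP0561
PCFP0562
PCFP0563
PCFP0564
PCFP0565
PCFP0566
PCFP0567
PCFP0568
PCFP0569
PCFP0570
PCFP0571
PCFP0572
PCFP0573
PCFP0574
PCFP0575
PCFP0576
PCFP0577
PCFP0578
PCFP0579
PCFP0580
PCFP0581
PCFP0582
PCFP0583
PCFP0584
PCFP0585
PCFP0586
PCFP0587
PCFP0588
PCFP0589
PCFP0590
PCFP0591
PCFP0592
PCFP0593
PCFP0594
PCFP0595
PCFP0596
PCFP0597
PCFP0598
PCFP0599
PCFP0600
PCFP0601
PCFP0602
PCFP0603
PCFP0604
PCFP0605
PCFP0606
PCFP0607
PCFP0608
PCFP0609
PCFP0610
PCFP0611
PCFP0612
PCFP0613
PCFP0614
PCFP0615
PCFP0616
PCFP0617
PCFP0618
PCFP0619
PCFP0620
PCFP0621
PCFP0622
PCFP0623
PCFP0624
PCFP0625
PCFP0626
PCFP0627
PCFP0628
PCFP0629
PCFP0630
PCFP0631
PCFP0632
PCFP0633
PCFP0634
PCFP0635
PCFP0636
PCFP0637
PCFP0638
PCFP0639
PCFP0640
PCFP0641
PCFP0642
PCFP0643
PCFP0644
PCFP0645
PCFP0646
PCFP0647
PCFP0648
PCFP0649
PCFP0650
PCFP0651
PCFP0652
PCFP0653
PCFP0654
PCFP0655
PCFP0656
PCFP0657
PCFP0658
PCFP0659
PCFP0660
PCFP0661
PCFP0662
PCFP0663
PCFP0664
PCFP0665
PCFP0666
PCFP0667
PCFP0668
PCFP0669
PCFP0670
PCFP0671
PCFP0672
PCFP0673
PCFP0674
PCFP0675
PCFP0676
PCFP0677
PCFP0678
PCFP0679
PCFP0680
PCFP0681
PCFP0682
PCFP0683
PCFP0684
PCFP0685
PCFP0686
PCFP0687
PCFP0688
PCFP0689
PCFP0690
PCFP0691
PCFP0692
PCFP0693
PCFP0694
PCFP0695
PCFP0696
PCFP0697
PCFP0698
PCFP0699
PCFP0700
PCFP0701
PCFP0702
PCFP0703
PCFP0704
PCFP0705
PCFP0706
PCFP0707
PCFP0708
PCFP0709
PCFP0710
PCFP0711
PCFP0712
PCFP0713
PCFP0714
PCFP0715
PCFP0716
PCFP0717
PCFP0718
PCFP0719
PCFP0720
PCFP0721
PCFP0722
PCFP0723
PCFP0724
PCFP0725
PCFP0726
PCFP0727
PCFP0728
PCFP0729
PCFP0730
PCFP0731
PCFP0732
PCFP0733
PCFP0734
PCFP0735
PCFP0736
PCFP0737
PCFP0738
PCFP0739
PCFP0740
PCFP0741
PCFP0742
PCFP0743
PCFP0744
PCFP0745
PCFP0746
PCFP0747
PCFP0748
PCFP0749
PCFP0750
PCFP0751
PCFP0752
PCFP0753
PCFP0754
PCFP0755
PCFP0756
PCFP0757
PCFP0758
PCFP0759
PCFP0760
PCFP0761
PCFP0762
PCFP0763
PCFP0764
PCFP0765
PCFP0766
PCFP0767
PCFP0768
PCFP0769
PCFP0770
PCFP0771
PCFP0772
PCFP0773
PCFP0774
PCFP0775
PCFP0776
PCFP0777
PCFP0778
PCFP0779
PCFP0780
PCFP0781
PCFP0782
PCFP0783
PCFP0784
PCFP0785
PCFP0786
PCFP0787
PCFP0788
PCFP0789
PCFP0790
PCFP0791
PCFP0792
PCFP0793
PCFP0794
PCFP0795
PCFP0796
PCFP0797
PCFP0798
PCFP0799
PCFP0800
PCFP0801
PCFP0802
PCFP0803
PCFP0804
PCFP0805
PCFP0806
PCFP0807
PCFP0808
PCFP0809
PCFP0810
PCFP0811
PCFP0812
PCFP0813
PCFP0814
PCFP0815
PCFP0816
PCFP0817
PCFP0818
PCFP0819
PCFP0820
PCFP0821
PCFP0822
PCFP0823
PCFP0824
PCFP0825
PCFP0826
PCFP0827
PCFP0828
PCFP0829
PCFP0830
PCFP0831
PCFP0832
PCFP0833
PCFP0834
PCFP0835
PCFP0836
PCFP0837
PCFP0838
PCFP0839
PCFP0840
PCFP0841
PCFP0842
PCFP0843
PCFP0844
PCFP0845
PCFP0846
PCFP0847
PCFP0848
PCFP0849
PCFP0850
PCFP0851
PCFP0852
PCFP0853
PCFP0854
PCFP0855
PCFP0856
PCFP0857
PCFP0858
PCFP0859
PCFP0860
PCFP0861
PCFP0862
PCFP0863
PCFP0864
PCFP0865
PCFP0866
PCFP0867
PCFP0868
PCFP0869
PCFP0870
PCFP0871
PCFP0872
PCFP0873
PCFP0874
PCFP0875
PCFP0876
PCFP0877
PCFP0878
PCFP0879
PCFP0880
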