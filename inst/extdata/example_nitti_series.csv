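patient_id,date,modality,value
EX01,2020-01-01,nitti_log_ohm,3.3423
EX01,2020-01-02,nitti_log_ohm,3.3824
EX01,2020-01-03,nitti_log_ohm,3.4155
EX01,2020-01-04,nitti_log_ohm,3.3309
EX01,2020-01-05,nitti_log_ohm,3.4117
EX01,2020-01-06,nitti_log_ohm,3.4018
EX01,2020-01-07,nitti_log_ohm,3.4051
EX01,2020-01-08,nitti_log_ohm,3.467
EX01,2020-01-09,nitti_log_ohm,3.3269
EX01,2020-01-10,nitti_log_ohm,3.476
EX01,2020-01-11,nitti_log_ohm,3.3553
EX01,2020-01-12,nitti_log_ohm,3.3321
EX01,2020-01-13,nitti_log_ohm,3.357
EX01,2020-01-14,nitti_log_ohm,3.4152
EX01,2020-01-15,nitti_log_ohm,3.4091
EX01,2020-01-16,nitti_log_ohm,3.3815
EX01,2020-01-17,nitti_log_ohm,3.3428
EX01,2020-01-18,nitti_log_ohm,3.3611
EX01,2020-01-19,nitti_log_ohm,3.4735
EX01,2020-01-20,nitti_log_ohm,3.412
EX01,2020-01-21,nitti_log_ohm,3.3653
EX01,2020-01-22,nitti_log_ohm,3.3435
EX01,2020-01-23,nitti_log_ohm,3.3878
EX01,2020-01-24,nitti_log_ohm,3.3
EX01,2020-01-25,nitti_log_ohm,3.3709
EX01,2020-01-26,nitti_log_ohm,3.3555
EX01,2020-01-27,nitti_log_ohm,3.4696
EX01,2020-01-28,nitti_log_ohm,3.4607
EX01,2020-01-29,nitti_log_ohm,3.3957
EX01,2020-01-30,nitti_log_ohm,3.3318
EX01,2020-01-31,nitti_log_ohm,3.454
EX01,2020-02-01,nitti_log_ohm,3.4511
EX01,2020-02-02,nitti_log_ohm,3.4437
EX01,2020-02-03,nitti_log_ohm,3.4442
EX01,2020-02-04,nitti_log_ohm,3.3789
EX01,2020-02-05,nitti_log_ohm,3.4423
EX01,2020-02-06,nitti_log_ohm,3.478
EX01,2020-02-07,nitti_log_ohm,3.4023
EX01,2020-02-08,nitti_log_ohm,3.3412
EX01,2020-02-09,nitti_log_ohm,3.4476
EX01,2020-02-10,nitti_log_ohm,3.4472
EX01,2020-02-11,nitti_log_ohm,3.3814
EX01,2020-02-12,nitti_log_ohm,3.5019
EX01,2020-02-13,nitti_log_ohm,3.3523
EX01,2020-02-14,nitti_log_ohm,3.4209
EX01,2020-02-15,nitti_log_ohm,3.2641
EX01,2020-02-16,nitti_log_ohm,3.3903
EX01,2020-02-17,nitti_log_ohm,3.4679
EX01,2020-02-18,nitti_log_ohm,3.3727
EX01,2020-02-19,nitti_log_ohm,3.3461
EX01,2020-02-20,nitti_log_ohm,3.4436
EX01,2020-02-21,nitti_log_ohm,3.3514
EX01,2020-02-22,nitti_log_ohm,3.416
EX01,2020-02-23,nitti_log_ohm,3.2958
EX01,2020-02-24,nitti_log_ohm,3.3153
EX01,2020-02-25,nitti_log_ohm,3.3728
EX01,2020-02-26,nitti_log_ohm,3.3379
EX01,2020-02-27,nitti_log_ohm,3.4817
EX01,2020-02-28,nitti_log_ohm,3.455
EX01,2020-02-29,nitti_log_ohm,3.3529
EX01,2020-03-01,nitti_log_ohm,3.4211
EX01,2020-03-02,nitti_log_ohm,3.4284
EX01,2020-03-03,nitti_log_ohm,3.3754
EX01,2020-03-04,nitti_log_ohm,3.3678
EX01,2020-03-05,nitti_log_ohm,3.4038
EX01,2020-03-06,nitti_log_ohm,3.2911
EX01,2020-03-07,nitti_log_ohm,3.2815
EX01,2020-03-08,nitti_log_ohm,3.3506
EX01,2020-03-09,nitti_log_ohm,3.2027
EX01,2020-03-10,nitti_log_ohm,3.2778
EX01,2020-03-11,nitti_log_ohm,3.2515
EX01,2020-03-12,nitti_log_ohm,3.268
EX01,2020-03-13,nitti_log_ohm,3.2881
EX01,2020-03-14,nitti_log_ohm,3.2294
EX01,2020-03-15,nitti_log_ohm,3.2139
EX01,2020-03-16,nitti_log_ohm,3.2315
EX01,2020-03-17,nitti_log_ohm,3.2464
EX01,2020-03-18,nitti_log_ohm,3.183
EX01,2020-03-19,nitti_log_ohm,3.0874
EX01,2020-03-20,nitti_log_ohm,3.1239
EX01,2020-03-21,nitti_log_ohm,3.2241
EX01,2020-03-22,nitti_log_ohm,3.0855
EX01,2020-03-23,nitti_log_ohm,3.1347
EX01,2020-03-24,nitti_log_ohm,3.1535
EX01,2020-03-25,nitti_log_ohm,3.1143
EX01,2020-03-26,nitti_log_ohm,3.0529
EX01,2020-03-27,nitti_log_ohm,3.0531
EX01,2020-03-28,nitti_log_ohm,2.9735
EX01,2020-03-29,nitti_log_ohm,3.0397
EX01,2020-03-30,nitti_log_ohm,2.9468
EX01,2020-03-31,nitti_log_ohm,2.9488
EX01,2020-04-01,nitti_log_ohm,2.9406
EX01,2020-04-02,nitti_log_ohm,2.9609
EX01,2020-04-03,nitti_log_ohm,3.0632
EX01,2020-04-04,nitti_log_ohm,2.9765
EX01,2020-04-05,nitti_log_ohm,2.9958
EX01,2020-04-06,nitti_log_ohm,2.9723
EX01,2020-04-07,nitti_log_ohm,3.0325
EX01,2020-04-08,nitti_log_ohm,3.0559
EX01,2020-04-09,nitti_log_ohm,2.9874
EX01,2020-04-10,nitti_log_ohm,3.037
EX01,2020-04-11,nitti_log_ohm,2.9757
EX01,2020-04-12,nitti_log_ohm,3.0632
EX01,2020-04-13,nitti_log_ohm,3.0361
EX01,2020-04-14,nitti_log_ohm,3.061
EX01,2020-04-15,nitti_log_ohm,3.0365
EX01,2020-04-16,nitti_log_ohm,3.0124
EX01,2020-04-17,nitti_log_ohm,2.8861
EX01,2020-04-18,nitti_log_ohm,2.959
EX01,2020-04-19,nitti_log_ohm,3.0289
EX01,2020-04-20,nitti_log_ohm,2.9722
EX01,2020-04-21,nitti_log_ohm,2.9832
EX01,2020-04-22,nitti_log_ohm,2.9752
EX01,2020-04-23,nitti_log_ohm,3.0971
EX01,2020-04-24,nitti_log_ohm,2.9567
EX01,2020-04-25,nitti_log_ohm,2.9728
EX01,2020-04-26,nitti_log_ohm,3.0009
EX01,2020-04-27,nitti_log_ohm,3.0129
EX01,2020-04-28,nitti_log_ohm,3.0113
EX01,2020-04-29,nitti_log_ohm,2.997
EX01,2020-04-30,nitti_log_ohm,2.9103
EX01,2020-05-01,nitti_log_ohm,3.0221
EX01,2020-05-02,nitti_log_ohm,3.031
EX01,2020-05-03,nitti_log_ohm,2.9709
EX01,2020-05-04,nitti_log_ohm,3.0405
EX01,2020-05-05,nitti_log_ohm,2.9543
EX01,2020-05-06,nitti_log_ohm,3.0232
EX01,2020-05-07,nitti_log_ohm,2.9602
EX01,2020-05-08,nitti_log_ohm,2.8965
EX01,2020-05-09,nitti_log_ohm,3.0694
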