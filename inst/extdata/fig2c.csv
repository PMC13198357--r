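#fixture=fig2c
#mechanism=ORT_FREE_WALL
#synthetic=TRUE
#induction_train_end=4480
time_ms,channel,kind,origin
0.0,RVA,STIM,PACED
150.0,CS_PROX,A,CONDUCTED
600.0,RVA,STIM,PACED
750.0,CS_PROX,A,CONDUCTED
1200.0,RVA,STIM,PACED
1350.0,CS_PROX,A,CONDUCTED
1800.0,RVA,STIM,PACED
1950.0,CS_PROX,A,CONDUCTED
2400.0,RVA,STIM,PACED
2550.0,CS_PROX,A,CONDUCTED
3000.0,RVA,STIM,PACED
3150.0,CS_PROX,A,CONDUCTED
3600.0,RVA,STIM,PACED
3750.0,CS_PROX,A,CONDUCTED
4200.0,RVA,STIM,PACED
4350.0,CS_PROX,A,CONDUCTED
4480.0,RVA,STIM,PACED
4720.0,CS_PROX,A,CONDUCTED
4740.0,HIS,A,CONDUCTED
4760.0,HRA,A,CONDUCTED
4810.0,HIS,H,CONDUCTED
4882.0,RVA,V,CONDUCTED
5060.0,CS_PROX,A,CONDUCTED
5080.0,HRA,A,CONDUCTED
5100.0,HIS,A,CONDUCTED
5170.0,HIS,H,CONDUCTED
5242.0,RVA,V,CONDUCTED
5420.0,CS_PROX,A,CONDUCTED
5440.0,HRA,A,CONDUCTED
5460.0,HIS,A,CONDUCTED
5530.0,HIS,H,CONDUCTED
5602.0,RVA,V,CONDUCTED
5780.0,CS_PROX,A,CONDUCTED
5800.0,HRA,A,CONDUCTED
5820.0,HIS,A,CONDUCTED
5890.0,HIS,H,CONDUCTED
5962.0,RVA,V,CONDUCTED
6140.0,CS_PROX,A,CONDUCTED
6160.0,HRA,A,CONDUCTED
6180.0,HIS,A,CONDUCTED
6250.0,HIS,H,CONDUCTED
6322.0,RVA,V,CONDUCTED
6500.0,CS_PROX,A,CONDUCTED
6520.0,HRA,A,CONDUCTED
6540.0,HIS,A,CONDUCTED
6610.0,HIS,H,CONDUCTED
6682.0,RVA,V,CONDUCTED
6860.0,CS_PROX,A,CONDUCTED
6880.0,HRA,A,CONDUCTED
6900.0,HIS,A,CONDUCTED
6970.0,HIS,H,CONDUCTED
7042.0,RVA,V,CONDUCTED
7220.0,CS_PROX,A,CONDUCTED
7240.0,HRA,A,CONDUCTED
7260.0,HIS,A,CONDUCTED
7330.0,HIS,H,CONDUCTED
7402.0,RVA,V,CONDUCTED
7580.0,CS_PROX,A,CONDUCTED
7600.0,HRA,A,CONDUCTED
7620.0,HIS,A,CONDUCTED
7690.0,HIS,H,CONDUCTED
7762.0,RVA,V,CONDUCTED
7940.0,CS_PROX,A,CONDUCTED
7960.0,HRA,A,CONDUCTED
7980.0,HIS,A,CONDUCTED
8050.0,HIS,H,CONDUCTED
8122.0,RVA,V,CONDUCTED
8300.0,CS_PROX,A,CONDUCTED
8320.0,HRA,A,CONDUCTED
8340.0,HIS,A,CONDUCTED
8410.0,HIS,H,CONDUCTED
8482.0,RVA,V,CONDUCTED
8660.0,CS_PROX,A,CONDUCTED
8680.0,HRA,A,CONDUCTED
8700.0,HIS,A,CONDUCTED
8770.0,HIS,H,CONDUCTED
8842.0,RVA,V,CONDUCTED
9020.0,CS_PROX,A,CONDUCTED
9040.0,HRA,A,CONDUCTED
9060.0,HIS,A,CONDUCTED
9130.0,HIS,H,CONDUCTED
9202.0,RVA,V,CONDUCTED
9380.0,CS_PROX,A,CONDUCTED
9400.0,HRA,A,CONDUCTED
9420.0,HIS,A,CONDUCTED
9490.0,HIS,H,CONDUCTED
9562.0,RVA,V,CONDUCTED
9740.0,CS_PROX,A,CONDUCTED
9760.0,HRA,A,CONDUCTED
9780.0,HIS,A,CONDUCTED
9850.0,HIS,H,CONDUCTED
9922.0,RVA,V,CONDUCTED
10100.0,CS_PROX,A,CONDUCTED
10120.0,HRA,A,CONDUCTED
10140.0,HIS,A,CONDUCTED
10210.0,HIS,H,CONDUCTED
10282.0,RVA,V,CONDUCTED
10460.0,CS_PROX,A,CONDUCTED
10480.0,HRA,A,CONDUCTED
10500.0,HIS,A,CONDUCTED
10570.0,HIS,H,CONDUCTED
10642.0,RVA,V,CONDUCTED
10820.0,CS_PROX,A,CONDUCTED
10840.0,HRA,A,CONDUCTED
10860.0,HIS,A,CONDUCTED
10930.0,HIS,H,CONDUCTED
11002.0,RVA,V,CONDUCTED
11180.0,CS_PROX,A,CONDUCTED
11200.0,HRA,A,CONDUCTED
11220.0,HIS,A,CONDUCTED
11290.0,HIS,H,CONDUCTED
11362.0,RVA,V,CONDUCTED
11540.0,CS_PROX,A,CONDUCTED
11560.0,HRA,A,CONDUCTED
11580.0,HIS,A,CONDUCTED
11650.0,HIS,H,CONDUCTED
11722.0,RVA,V,CONDUCTED
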