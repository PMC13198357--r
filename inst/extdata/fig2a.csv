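#fixture=fig2a
#mechanism=AT
#synthetic=TRUE
#induction_train_end=2450
time_ms,channel,kind,origin
0.0,RVA,STIM,PACED
200.0,CS_PROX,A,CONDUCTED
220.0,HIS,A,CONDUCTED
235.0,HRA,A,CONDUCTED
350.0,RVA,STIM,PACED
550.0,CS_PROX,A,CONDUCTED
570.0,HIS,A,CONDUCTED
585.0,HRA,A,CONDUCTED
700.0,RVA,STIM,PACED
900.0,CS_PROX,A,CONDUCTED
920.0,HIS,A,CONDUCTED
935.0,HRA,A,CONDUCTED
1050.0,RVA,STIM,PACED
1250.0,CS_PROX,A,CONDUCTED
1270.0,HIS,A,CONDUCTED
1285.0,HRA,A,CONDUCTED
1400.0,RVA,STIM,PACED
1600.0,CS_PROX,A,CONDUCTED
1620.0,HIS,A,CONDUCTED
1635.0,HRA,A,CONDUCTED
1750.0,RVA,STIM,PACED
1950.0,CS_PROX,A,CONDUCTED
1970.0,HIS,A,CONDUCTED
1985.0,HRA,A,CONDUCTED
2100.0,RVA,STIM,PACED
2300.0,CS_PROX,A,CONDUCTED
2320.0,HIS,A,CONDUCTED
2335.0,HRA,A,CONDUCTED
2450.0,RVA,STIM,PACED
2650.0,CS_PROX,A,CONDUCTED
2670.0,HIS,A,CONDUCTED
2685.0,HRA,A,CONDUCTED
3100.0,HRA,A,CONDUCTED
3130.0,HIS,A,CONDUCTED
3150.0,CS_PROX,A,CONDUCTED
3280.0,HIS,H,CONDUCTED
3384.0,RVA,V,CONDUCTED
3550.0,HRA,A,CONDUCTED
3580.0,HIS,A,CONDUCTED
3600.0,CS_PROX,A,CONDUCTED
3730.0,HIS,H,CONDUCTED
3834.0,RVA,V,CONDUCTED
4000.0,HRA,A,CONDUCTED
4030.0,HIS,A,CONDUCTED
4050.0,CS_PROX,A,CONDUCTED
4180.0,HIS,H,CONDUCTED
4284.0,RVA,V,CONDUCTED
4450.0,HRA,A,CONDUCTED
4480.0,HIS,A,CONDUCTED
4500.0,CS_PROX,A,CONDUCTED
4630.0,HIS,H,CONDUCTED
4734.0,RVA,V,CONDUCTED
4900.0,HRA,A,CONDUCTED
4930.0,HIS,A,CONDUCTED
4950.0,CS_PROX,A,CONDUCTED
5080.0,HIS,H,CONDUCTED
5184.0,RVA,V,CONDUCTED
5350.0,HRA,A,CONDUCTED
5380.0,HIS,A,CONDUCTED
5400.0,CS_PROX,A,CONDUCTED
5530.0,HIS,H,CONDUCTED
5634.0,RVA,V,CONDUCTED
5800.0,HRA,A,CONDUCTED
5830.0,HIS,A,CONDUCTED
5850.0,CS_PROX,A,CONDUCTED
5980.0,HIS,H,CONDUCTED
6084.0,RVA,V,CONDUCTED
6250.0,HRA,A,CONDUCTED
6280.0,HIS,A,CONDUCTED
6300.0,CS_PROX,A,CONDUCTED
6430.0,HIS,H,CONDUCTED
6534.0,RVA,V,CONDUCTED
6700.0,HRA,A,CONDUCTED
6730.0,HIS,A,CONDUCTED
6750.0,CS_PROX,A,CONDUCTED
6880.0,HIS,H,CONDUCTED
6984.0,RVA,V,CONDUCTED
7150.0,HRA,A,CONDUCTED
7180.0,HIS,A,CONDUCTED
7200.0,CS_PROX,A,CONDUCTED
7330.0,HIS,H,CONDUCTED
7434.0,RVA,V,CONDUCTED
7600.0,HRA,A,CONDUCTED
7630.0,HIS,A,CONDUCTED
7650.0,CS_PROX,A,CONDUCTED
7780.0,HIS,H,CONDUCTED
7884.0,RVA,V,CONDUCTED
8050.0,HRA,A,CONDUCTED
8080.0,HIS,A,CONDUCTED
8100.0,CS_PROX,A,CONDUCTED
8230.0,HIS,H,CONDUCTED
8334.0,RVA,V,CONDUCTED
8500.0,HRA,A,CONDUCTED
8530.0,HIS,A,CONDUCTED
8550.0,CS_PROX,A,CONDUCTED
8680.0,HIS,H,CONDUCTED
8784.0,RVA,V,CONDUCTED
8950.0,HRA,A,CONDUCTED
8980.0,HIS,A,CONDUCTED
9000.0,CS_PROX,A,CONDUCTED
9130.0,HIS,H,CONDUCTED
9234.0,RVA,V,CONDUCTED
9400.0,HRA,A,CONDUCTED
9430.0,HIS,A,CONDUCTED
9450.0,CS_PROX,A,CONDUCTED
9580.0,HIS,H,CONDUCTED
9684.0,RVA,V,CONDUCTED
9850.0,HRA,A,CONDUCTED
9880.0,HIS,A,CONDUCTED
9900.0,CS_PROX,A,CONDUCTED
10030.0,HIS,H,CONDUCTED
10134.0,RVA,V,CONDUCTED
10300.0,HRA,A,CONDUCTED
10330.0,HIS,A,CONDUCTED
10350.0,CS_PROX,A,CONDUCTED
10480.0,HIS,H,CONDUCTED
10584.0,RVA,V,CONDUCTED
10750.0,HRA,A,CONDUCTED
10780.0,HIS,A,CONDUCTED
10800.0,CS_PROX,A,CONDUCTED
10930.0,HIS,H,CONDUCTED
11034.0,RVA,V,CONDUCTED
11200.0,HRA,A,CONDUCTED
11230.0,HIS,A,CONDUCTED
11250.0,CS_PROX,A,CONDUCTED
11380.0,HIS,H,CONDUCTED
11484.0,RVA,V,CONDUCTED
11650.0,HRA,A,CONDUCTED
11680.0,HIS,A,CONDUCTED
11700.0,CS_PROX,A,CONDUCTED
11830.0,HIS,H,CONDUCTED
11934.0,RVA,V,CONDUCTED
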