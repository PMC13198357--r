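#fixture=fig2b
#mechanism=AVNRT_FAST_SLOW
#synthetic=TRUE
#induction_train_end=4500
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
4500.0,RVA,STIM,PACED
4800.0,CS_PROX,A,CONDUCTED
4820.0,HIS,A,CONDUCTED
4840.0,HRA,A,CONDUCTED
4930.0,HIS,H,CONDUCTED
5034.0,RVA,V,CONDUCTED
5180.0,CS_PROX,A,CONDUCTED
5200.0,HRA,A,CONDUCTED
5220.0,HIS,A,CONDUCTED
5330.0,HIS,H,CONDUCTED
5434.0,RVA,V,CONDUCTED
5580.0,CS_PROX,A,CONDUCTED
5600.0,HRA,A,CONDUCTED
5620.0,HIS,A,CONDUCTED
5730.0,HIS,H,CONDUCTED
5834.0,RVA,V,CONDUCTED
5980.0,CS_PROX,A,CONDUCTED
6000.0,HRA,A,CONDUCTED
6020.0,HIS,A,CONDUCTED
6130.0,HIS,H,CONDUCTED
6234.0,RVA,V,CONDUCTED
6380.0,CS_PROX,A,CONDUCTED
6400.0,HRA,A,CONDUCTED
6420.0,HIS,A,CONDUCTED
6530.0,HIS,H,CONDUCTED
6634.0,RVA,V,CONDUCTED
6780.0,CS_PROX,A,CONDUCTED
6800.0,HRA,A,CONDUCTED
6820.0,HIS,A,CONDUCTED
6930.0,HIS,H,CONDUCTED
7034.0,RVA,V,CONDUCTED
7180.0,CS_PROX,A,CONDUCTED
7200.0,HRA,A,CONDUCTED
7220.0,HIS,A,CONDUCTED
7330.0,HIS,H,CONDUCTED
7434.0,RVA,V,CONDUCTED
7580.0,CS_PROX,A,CONDUCTED
7600.0,HRA,A,CONDUCTED
7620.0,HIS,A,CONDUCTED
7730.0,HIS,H,CONDUCTED
7834.0,RVA,V,CONDUCTED
7980.0,CS_PROX,A,CONDUCTED
8000.0,HRA,A,CONDUCTED
8020.0,HIS,A,CONDUCTED
8130.0,HIS,H,CONDUCTED
8234.0,RVA,V,CONDUCTED
8380.0,CS_PROX,A,CONDUCTED
8400.0,HRA,A,CONDUCTED
8420.0,HIS,A,CONDUCTED
8530.0,HIS,H,CONDUCTED
8634.0,RVA,V,CONDUCTED
8780.0,CS_PROX,A,CONDUCTED
8800.0,HRA,A,CONDUCTED
8820.0,HIS,A,CONDUCTED
8930.0,HIS,H,CONDUCTED
9034.0,RVA,V,CONDUCTED
9180.0,CS_PROX,A,CONDUCTED
9200.0,HRA,A,CONDUCTED
9220.0,HIS,A,CONDUCTED
9330.0,HIS,H,CONDUCTED
9434.0,RVA,V,CONDUCTED
9580.0,CS_PROX,A,CONDUCTED
9600.0,HRA,A,CONDUCTED
9620.0,HIS,A,CONDUCTED
9730.0,HIS,H,CONDUCTED
9834.0,RVA,V,CONDUCTED
9980.0,CS_PROX,A,CONDUCTED
10000.0,HRA,A,CONDUCTED
10020.0,HIS,A,CONDUCTED
10130.0,HIS,H,CONDUCTED
10234.0,RVA,V,CONDUCTED
10380.0,CS_PROX,A,CONDUCTED
10400.0,HRA,A,CONDUCTED
10420.0,HIS,A,CONDUCTED
10530.0,HIS,H,CONDUCTED
10634.0,RVA,V,CONDUCTED
10780.0,CS_PROX,A,CONDUCTED
10800.0,HRA,A,CONDUCTED
10820.0,HIS,A,CONDUCTED
10930.0,HIS,H,CONDUCTED
11034.0,RVA,V,CONDUCTED
11180.0,CS_PROX,A,CONDUCTED
11200.0,HRA,A,CONDUCTED
11220.0,HIS,A,CONDUCTED
11330.0,HIS,H,CONDUCTED
11434.0,RVA,V,CONDUCTED
11580.0,CS_PROX,A,CONDUCTED
11600.0,HRA,A,CONDUCTED
11620.0,HIS,A,CONDUCTED
11730.0,HIS,H,CONDUCTED
11834.0,RVA,V,CONDUCTED
11980.0,CS_PROX,A,CONDUCTED
12000.0,HRA,A,CONDUCTED
12020.0,HIS,A,CONDUCTED
12130.0,HIS,H,CONDUCTED
12234.0,RVA,V,CONDUCTED
12380.0,CS_PROX,A,CONDUCTED
12400.0,HRA,A,CONDUCTED
12420.0,HIS,A,CONDUCTED
12530.0,HIS,H,CONDUCTED
12634.0,RVA,V,CONDUCTED
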