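#fixture=fig3
#mechanism=ORT_SEPTAL
#synthetic=TRUE
#induction_train_end=4500
#vop_first_stim=13522
#vop_train_end=16942
#vop_pcl=380
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
4680.0,CS_MID,A,CONDUCTED
4700.0,HIS,A,CONDUCTED
5080.0,HIS,H,CONDUCTED
5122.0,RVA,V,CONDUCTED
5244.0,CS_MID,A,CONDUCTED
5264.0,HIS,A,CONDUCTED
5480.0,HIS,H,CONDUCTED
5522.0,RVA,V,CONDUCTED
5644.0,CS_MID,A,CONDUCTED
5664.0,HIS,A,CONDUCTED
5880.0,HIS,H,CONDUCTED
5922.0,RVA,V,CONDUCTED
6044.0,CS_MID,A,CONDUCTED
6064.0,HIS,A,CONDUCTED
6280.0,HIS,H,CONDUCTED
6322.0,RVA,V,CONDUCTED
6444.0,CS_MID,A,CONDUCTED
6464.0,HIS,A,CONDUCTED
6680.0,HIS,H,CONDUCTED
6722.0,RVA,V,CONDUCTED
6844.0,CS_MID,A,CONDUCTED
6864.0,HIS,A,CONDUCTED
7080.0,HIS,H,CONDUCTED
7122.0,RVA,V,CONDUCTED
7244.0,CS_MID,A,CONDUCTED
7264.0,HIS,A,CONDUCTED
7480.0,HIS,H,CONDUCTED
7522.0,RVA,V,CONDUCTED
7644.0,CS_MID,A,CONDUCTED
7664.0,HIS,A,CONDUCTED
7880.0,HIS,H,CONDUCTED
7922.0,RVA,V,CONDUCTED
8044.0,CS_MID,A,CONDUCTED
8064.0,HIS,A,CONDUCTED
8280.0,HIS,H,CONDUCTED
8322.0,RVA,V,CONDUCTED
8444.0,CS_MID,A,CONDUCTED
8464.0,HIS,A,CONDUCTED
8680.0,HIS,H,CONDUCTED
8722.0,RVA,V,CONDUCTED
8844.0,CS_MID,A,CONDUCTED
8864.0,HIS,A,CONDUCTED
9080.0,HIS,H,CONDUCTED
9122.0,RVA,V,CONDUCTED
9244.0,CS_MID,A,CONDUCTED
9264.0,HIS,A,CONDUCTED
9480.0,HIS,H,CONDUCTED
9522.0,RVA,V,CONDUCTED
9644.0,CS_MID,A,CONDUCTED
9664.0,HIS,A,CONDUCTED
9880.0,HIS,H,CONDUCTED
9922.0,RVA,V,CONDUCTED
10044.0,CS_MID,A,CONDUCTED
10064.0,HIS,A,CONDUCTED
10280.0,HIS,H,CONDUCTED
10322.0,RVA,V,CONDUCTED
10444.0,CS_MID,A,CONDUCTED
10464.0,HIS,A,CONDUCTED
10680.0,HIS,H,CONDUCTED
10722.0,RVA,V,CONDUCTED
10844.0,CS_MID,A,CONDUCTED
10864.0,HIS,A,CONDUCTED
11080.0,HIS,H,CONDUCTED
11122.0,RVA,V,CONDUCTED
11244.0,CS_MID,A,CONDUCTED
11264.0,HIS,A,CONDUCTED
11480.0,HIS,H,CONDUCTED
11522.0,RVA,V,CONDUCTED
11644.0,CS_MID,A,CONDUCTED
11664.0,HIS,A,CONDUCTED
11880.0,HIS,H,CONDUCTED
11922.0,RVA,V,CONDUCTED
12044.0,CS_MID,A,CONDUCTED
12064.0,HIS,A,CONDUCTED
12280.0,HIS,H,CONDUCTED
12322.0,RVA,V,CONDUCTED
12444.0,CS_MID,A,CONDUCTED
12464.0,HIS,A,CONDUCTED
12680.0,HIS,H,CONDUCTED
12722.0,RVA,V,CONDUCTED
12844.0,CS_MID,A,CONDUCTED
12864.0,HIS,A,CONDUCTED
13080.0,HIS,H,CONDUCTED
13122.0,RVA,V,CONDUCTED
13522.0,RVA,STIM,PACED
13692.0,CS_MID,A,CONDUCTED
13712.0,HIS,A,CONDUCTED
13902.0,RVA,STIM,PACED
14072.0,CS_MID,A,CONDUCTED
14092.0,HIS,A,CONDUCTED
14282.0,RVA,STIM,PACED
14452.0,CS_MID,A,CONDUCTED
14472.0,HIS,A,CONDUCTED
14662.0,RVA,STIM,PACED
14832.0,CS_MID,A,CONDUCTED
14852.0,HIS,A,CONDUCTED
15042.0,RVA,STIM,PACED
15212.0,CS_MID,A,CONDUCTED
15232.0,HIS,A,CONDUCTED
15422.0,RVA,STIM,PACED
15592.0,CS_MID,A,CONDUCTED
15612.0,HIS,A,CONDUCTED
15802.0,RVA,STIM,PACED
15972.0,CS_MID,A,CONDUCTED
15992.0,HIS,A,CONDUCTED
16182.0,RVA,STIM,PACED
16352.0,CS_MID,A,CONDUCTED
16372.0,HIS,A,CONDUCTED
16562.0,RVA,STIM,PACED
16732.0,CS_MID,A,CONDUCTED
16752.0,HIS,A,CONDUCTED
16942.0,RVA,STIM,PACED
17112.0,CS_MID,A,CONDUCTED
17132.0,HIS,A,CONDUCTED
17482.0,HIS,H,CONDUCTED
17528.0,RVA,V,CONDUCTED
17650.0,CS_MID,A,CONDUCTED
17670.0,HIS,A,CONDUCTED
17886.0,HIS,H,CONDUCTED
17928.0,RVA,V,CONDUCTED
18050.0,CS_MID,A,CONDUCTED
18070.0,HIS,A,CONDUCTED
18286.0,HIS,H,CONDUCTED
18328.0,RVA,V,CONDUCTED
18450.0,CS_MID,A,CONDUCTED
18470.0,HIS,A,CONDUCTED
18686.0,HIS,H,CONDUCTED
18728.0,RVA,V,CONDUCTED
18850.0,CS_MID,A,CONDUCTED
18870.0,HIS,A,CONDUCTED
19086.0,HIS,H,CONDUCTED
19128.0,RVA,V,CONDUCTED
19250.0,CS_MID,A,CONDUCTED
19270.0,HIS,A,CONDUCTED
19486.0,HIS,H,CONDUCTED
19528.0,RVA,V,CONDUCTED
19650.0,CS_MID,A,CONDUCTED
19670.0,HIS,A,CONDUCTED
19886.0,HIS,H,CONDUCTED
19928.0,RVA,V,CONDUCTED
20050.0,CS_MID,A,CONDUCTED
20070.0,HIS,A,CONDUCTED
20286.0,HIS,H,CONDUCTED
20328.0,RVA,V,CONDUCTED
20450.0,CS_MID,A,CONDUCTED
20470.0,HIS,A,CONDUCTED
20686.0,HIS,H,CONDUCTED
20728.0,RVA,V,CONDUCTED
20850.0,CS_MID,A,CONDUCTED
20870.0,HIS,A,CONDUCTED
21086.0,HIS,H,CONDUCTED
21128.0,RVA,V,CONDUCTED
21250.0,CS_MID,A,CONDUCTED
21270.0,HIS,A,CONDUCTED
21486.0,HIS,H,CONDUCTED
21528.0,RVA,V,CONDUCTED
21650.0,CS_MID,A,CONDUCTED
21670.0,HIS,A,CONDUCTED
21886.0,HIS,H,CONDUCTED
21928.0,RVA,V,CONDUCTED
22050.0,CS_MID,A,CONDUCTED
22070.0,HIS,A,CONDUCTED
22286.0,HIS,H,CONDUCTED
22328.0,RVA,V,CONDUCTED
22450.0,CS_MID,A,CONDUCTED
22470.0,HIS,A,CONDUCTED
22686.0,HIS,H,CONDUCTED
22728.0,RVA,V,CONDUCTED
22850.0,CS_MID,A,CONDUCTED
22870.0,HIS,A,CONDUCTED
23086.0,HIS,H,CONDUCTED
23128.0,RVA,V,CONDUCTED
23250.0,CS_MID,A,CONDUCTED
23270.0,HIS,A,CONDUCTED
23486.0,HIS,H,CONDUCTED
23528.0,RVA,V,CONDUCTED
23650.0,CS_MID,A,CONDUCTED
23670.0,HIS,A,CONDUCTED
23886.0,HIS,H,CONDUCTED
23928.0,RVA,V,CONDUCTED
24050.0,CS_MID,A,CONDUCTED
24070.0,HIS,A,CONDUCTED
24286.0,HIS,H,CONDUCTED
24328.0,RVA,V,CONDUCTED
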