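redox,variant,quantity,value,sd
oxidized,WT,"k_1,2",4.50,0.81
oxidized,WT,"k_1,3",0.32,0.31
oxidized,WT,"k_2,1",2.38,0.36
oxidized,WT,"k_2,3",0.78,0.26
oxidized,WT,"k_3,1",0.15,0.11
oxidized,WT,"k_3,2",1.07,0.24
oxidized,WT,pct_O1,23,1
oxidized,WT,pct_O2,44,3
oxidized,WT,pct_C,34,1
oxidized,WT,chi2_global,5.5,NA
oxidized,AA/AA,"k_1,2",2.14,0.14
oxidized,AA/AA,"k_1,3",0.63,0.23
oxidized,AA/AA,"k_2,1",1.59,0.13
oxidized,AA/AA,"k_2,3",1.03,0.09
oxidized,AA/AA,"k_3,1",0.66,0.15
oxidized,AA/AA,"k_3,2",0.95,0.11
oxidized,AA/AA,pct_O1,29,1
oxidized,AA/AA,pct_O2,36,2
oxidized,AA/AA,pct_C,35,2
oxidized,AA/AA,chi2_global,6.2,NA
oxidized,CC/AA,"k_1,2",4.43,0.05
oxidized,CC/AA,"k_1,3",0.34,0.13
oxidized,CC/AA,"k_2,1",2.39,0.09
oxidized,CC/AA,"k_2,3",0.67,0.06
oxidized,CC/AA,"k_3,1",0.12,0.02
oxidized,CC/AA,"k_3,2",0.94,0.06
oxidized,CC/AA,pct_O1,22,1
oxidized,CC/AA,pct_O2,43,1
oxidized,CC/AA,pct_C,35,1
oxidized,CC/AA,chi2_global,5.2,NA
oxidized,AA/CC,"k_1,2",2.73,0.36
oxidized,AA/CC,"k_1,3",0.26,0.28
oxidized,AA/CC,"k_2,1",1.51,0.11
oxidized,AA/CC,"k_2,3",0.68,0.12
oxidized,AA/CC,"k_3,1",0.48,0.24
oxidized,AA/CC,"k_3,2",0.66,0.24
oxidized,AA/CC,pct_O1,26,1
oxidized,AA/CC,pct_O2,42,2
oxidized,AA/CC,pct_C,32,1
oxidized,AA/CC,chi2_global,4.9,NA
oxidized,R300H,"k_1,2",1.97,0.41
oxidized,R300H,"k_1,3",0.51,0.47
oxidized,R300H,"k_2,1",1.35,0.22
oxidized,R300H,"k_2,3",0.70,0.55
oxidized,R300H,"k_3,1",0.09,0.11
oxidized,R300H,"k_3,2",1.20,0.16
oxidized,R300H,pct_O1,22,2
oxidized,R300H,pct_O2,39,4
oxidized,R300H,pct_C,39,2
oxidized,R300H,chi2_global,6.7,NA
oxidized,W396A,"k_1,2",1.36,0.14
oxidized,W396A,"k_1,3",1.38,0.09
oxidized,W396A,"k_2,1",1.51,0.39
oxidized,W396A,"k_2,3",0.80,0.11
oxidized,W396A,"k_3,1",0.13,0.04
oxidized,W396A,"k_3,2",0.93,0.16
oxidized,W396A,pct_O1,20,1
oxidized,W396A,pct_O2,32,2
oxidized,W396A,pct_C,49,1
oxidized,W396A,chi2_global,4.7,NA
reduced,WT,"k_1,2",8.49,1.95
reduced,WT,"k_1,3",0.36,0.33
reduced,WT,"k_2,1",6.28,1.07
reduced,WT,"k_2,3",0.11,0.06
reduced,WT,"k_3,1",1.39,0.84
reduced,WT,"k_3,2",0.40,0.21
reduced,WT,pct_O1,39,1
reduced,WT,pct_O2,51,3
reduced,WT,pct_C,9,2
reduced,WT,chi2_global,4.5,NA
reduced,AA/AA,"k_1,2",2.12,0.15
reduced,AA/AA,"k_1,3",0.39,0.34
reduced,AA/AA,"k_2,1",1.45,0.39
reduced,AA/AA,"k_2,3",0.75,0.59
reduced,AA/AA,"k_3,1",0.48,0.17
reduced,AA/AA,"k_3,2",0.97,0.23
reduced,AA/AA,pct_O1,28,1
reduced,AA/AA,pct_O2,37,2
reduced,AA/AA,pct_C,35,1
reduced,AA/AA,chi2_global,5.1,NA
reduced,CC/AA,"k_1,2",9.35,0.30
reduced,CC/AA,"k_1,3",0.99,0.66
reduced,CC/AA,"k_2,1",7.50,1.95
reduced,CC/AA,"k_2,3",0.75,1.19
reduced,CC/AA,"k_3,1",3.95,4.47
reduced,CC/AA,"k_3,2",2.05,2.72
reduced,CC/AA,pct_O1,41,1
reduced,CC/AA,pct_O2,49,3
reduced,CC/AA,pct_C,10,2
reduced,CC/AA,chi2_global,4.2,NA
reduced,AA/CC,"k_1,2",4.33,1.29
reduced,AA/CC,"k_1,3",1.03,1.04
reduced,AA/CC,"k_2,1",3.52,0.32
reduced,AA/CC,"k_2,3",0.27,0.09
reduced,AA/CC,"k_3,1",0.79,0.19
reduced,AA/CC,"k_3,2",0.50,0.50
reduced,AA/CC,pct_O1,37,3
reduced,AA/CC,pct_O2,45,6
reduced,AA/CC,pct_C,18,3
reduced,AA/CC,chi2_global,5.2,NA
reduced,R300H,"k_1,2",6.64,0.21
reduced,R300H,"k_1,3",0.94,1.29
reduced,R300H,"k_2,1",4.09,0.18
reduced,R300H,"k_2,3",0.17,0.13
reduced,R300H,"k_3,1",0.36,0.55
reduced,R300H,"k_3,2",0.68,0.60
reduced,R300H,pct_O1,33,1
reduced,R300H,pct_O2,53,1
reduced,R300H,pct_C,14,1
reduced,R300H,chi2_global,6.1,NA
reduced,W396A,"k_1,2",4.49,0.62
reduced,W396A,"k_1,3",0.78,0.09
reduced,W396A,"k_2,1",4.72,0.40
reduced,W396A,"k_2,3",0.16,0.05
reduced,W396A,"k_3,1",0.25,0.22
reduced,W396A,"k_3,2",1.30,0.11
reduced,W396A,pct_O1,37,1
reduced,W396A,pct_O2,40,2
reduced,W396A,pct_C,23,1
reduced,W396A,chi2_global,5.1,NA
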