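record_id,patient_id,bx_year,bx_type,day_after_tx,abo,hla_dsa,t,t_ifta,i,i_ifta,v,g,ptc,c4d,cg,cv,ci,ct,ptcbm,tma,pathologist_dx,expected_engine_dx,known_deviation
104347-2018-359,104347,2018,protocol,359,compatible,-,0,,0,,1,0,1,2,0,1,,,1,0,CA-AMR,A-TCMR,0
104461-2018-347,104461,2018,protocol,347,incompatible,-,0,,0,,0,1,0,0,0,0,,,0,0,A-AMR,no-rejection,0
104529-2019-359,104529,2019,protocol,359,incompatible,-,0,,0,,0,1,0,2,0,0,,,0,0,A-AMR,no-rejection,0
104601-2019-365,104601,2019,protocol,365,compatible,-,1,,0,,0,0,2,1,0,0,1,1,0,0,A-AMR,IFTA,1
104797-2019-58,104797,2019,follow-up,58,incompatible,-,0,,0,,0,0,1,2,2,3,1,1,0,0,CA-AMR,IFTA,0
104797-2019-24,104797,2019,follow-up,24,incompatible,-,0,,0,,0,0,1,0,0,3,,,0,0,A-AMR,no-rejection,0
104949-2020-12,104949,2020,for-cause,12,incompatible,-,1,,0,,0,0,1,2,0,0,,,0,0,A-AMR,no-rejection,0
105058-2021-105,105058,2021,protocol,105,incompatible,-,0,,0,,0,1,0,2,0,0,,,0,0,A-AMR,no-rejection,0
105139-2021-97,105139,2021,protocol,97,incompatible,-,0,,0,,0,0,2,1,0,0,1,1,0,0,A-AMR,IFTA,0
105178-2022-115,105178,2022,protocol,115,compatible,+,0,,0,,0,1,0,1,0,0,,,0,0,A-AMR,no-rejection,0
105182-2022-100,105182,2022,protocol,100,incompatible,-,0,,0,,0,0,1,3,0,0,,,0,0,A-AMR,no-rejection,0
105190-2022-89,105190,2022,protocol,89,incompatible,-,0,,0,,0,1,0,3,0,0,,,0,0,A-AMR,no-rejection,0
105194-2022-108,105194,2022,protocol,108,compatible,-,0,,0,,0,1,0,1,0,0,,,0,0,CA-AMR,no-rejection,0
105237-2022-6,105237,2022,for-cause,6,compatible,+,0,,1,,0,1,0,0,0,0,,,0,0,A-AMR,no-rejection,0
104309-2017-113,104309,2017,for-cause,113,compatible,-,2,,0,,0,1,1,0,0,0,,,0,0,BC,A-AMR,0
104431-2017-1092,104431,2017,for-cause,1092,incompatible,-,0,,0,,0,1,1,2,0,0,,,0,0,PGNMID recurrence,A-AMR,0
104488-2018-870,104488,2018,for-cause,870,compatible,-,3,,0,,0,0,2,0,0,0,,,0,0,FSGS recurrence,A-AMR,0
104553-2018-380,104553,2018,protocol,380,compatible,-,0,,0,,0,1,0,2,0,0,,,0,0,No rejection,A-AMR,0
104580-2018-86,104580,2018,protocol,86,compatible,+,0,,0,,0,0,2,0,0,0,,,0,0,No rejection,A-AMR,0
104580-2018-16,104580,2018,for-cause,16,compatible,+,0,,0,,0,0,2,1,0,0,,,0,0,Toxic tubulopathy,A-AMR,0
104805-2019-1083,104805,2019,for-cause,1083,compatible,-,1,,0,,0,0,2,2,0,0,,,1,0,CA-TCMR,A-AMR,0
104888-2019-677,104888,2019,for-cause,677,compatible,-,0,,0,,0,1,2,0,0,0,,,0,0,BKV nephropathy,A-AMR,0
104925-2020-28,104925,2020,for-cause,28,compatible,-,2,,0,,0,0,2,0,0,0,,,0,0,IF/TA,A-AMR,0
105064-2021-497,105064,2021,protocol,497,compatible,-,0,,0,,0,0,2,0,0,0,,,0,0,No rejection,CA-AMR,1
105128-2021-23,105128,2021,follow-up,23,incompatible,+,0,,0,,0,2,0,2,1,0,,,0,1,TMA,CA-AMR,0
105149-2021-21,105149,2021,for-cause,21,compatible,-,0,,0,,0,2,1,2,0,0,,,0,0,FSGS recurrence,A-AMR,0
105181-2021-50,105181,2021,for-cause,50,compatible,-,1,,1,,0,2,2,1,0,0,,,0,0,A-TCMR 1A,A-AMR,0
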