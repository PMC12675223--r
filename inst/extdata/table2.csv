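record_id,patient_id,bx_year,bx_type,day_after_tx,abo,hla_dsa,t,t_ifta,i,i_ifta,v,g,ptc,c4d,cg,cv,ci,ct,ptcbm,tma,pathologist_dx,expected_engine_dx,known_deviation
104805-2022-1083,104805,2022,protocol,1083,compatible,-,1,3,0,2,0,0,2,2,0,0,3,3,,0,CA-TCMR,A-AMR,0
104429-2018-361,104429,2018,for-cause,361,compatible,-,0,,0,1,0,0,0,0,0,0,0,0,,0,A-TCMR,no-rejection,0
104441-2021-1435,104441,2021,protocol,1435,incompatible,-,0,0,1,3,0,0,2,0,0,0,3,3,,0,CA-TCMR,IFTA,0
104597-2019-178,104597,2019,follow-up,178,compatible,-,2,,1,1,0,0,1,1,0,0,1,1,,0,A-TCMR,BC,0
104888-2021-677,104888,2021,for-cause,677,compatible,-,0,3,0,2,0,1,2,0,0,0,3,3,,0,CA-TCMR,A-AMR,0
104962-2021-431,104962,2021,protocol,431,compatible,-,0,1,0,1,0,0,0,0,0,0,1,1,,0,CA-TCMR,IFTA,0
104971-2020-88,104971,2020,protocol,88,incompatible,-,0,3,0,2,0,0,2,3,0,0,1,1,,0,CA-TCMR,IFTA,0
105181-2022-50,105181,2022,protocol,50,compatible,-,1,0,1,1,0,2,2,1,0,0,2,2,,0,A-TCMR,A-AMR,0
105165-2022-97,105165,2022,protocol,97,compatible,-,2,0,0,3,0,0,2,0,0,0,0,0,,0,BC,CA-TCMR,0
105168-2022-176,105168,2022,protocol,176,compatible,-,2,1,1,2,0,0,2,0,0,0,2,2,,0,BC,CA-TCMR,0
104347-2018-359,104347,2018,protocol,359,compatible,-,0,,0,,1,0,0,1,0,1,0,0,,0,CA-AMR,A-TCMR,0
104420-2019-649,104420,2019,for-cause,649,compatible,-,2,,0,2,0,0,2,0,0,0,0,0,,0,No rejection,CA-TCMR,0
104661-2019-373,104661,2019,protocol,373,compatible,-,2,,1,2,0,0,0,0,0,0,1,1,,0,No rejection,CA-TCMR,0
104336-2018-365,104336,2018,for-cause,365,compatible,-,3,,0,2,0,0,2,0,0,0,2,2,,0,No rejection,CA-TCMR,0
104851-2020-256,104851,2020,for-cause,256,compatible,-,0,3,0,2,0,0,2,0,0,0,2,2,,0,No rejection,CA-TCMR,0
105052-2021-206,105052,2021,for-cause,206,compatible,-,3,0,1,2,0,0,2,1,0,0,2,2,,0,No rejection,CA-TCMR,0
104395-2017-114,104395,2017,protocol,114,compatible,-,1,,0,,1,0,1,3,0,,0,0,,0,No rejection,A-TCMR,0
104396-2017-85,104396,2017,protocol,85,compatible,-,2,,2,,0,0,2,1,0,,1,1,,0,No rejection,A-TCMR,0
104866-2020-368,104866,2020,protocol,368,compatible,-,0,0,0,0,1,0,1,0,0,0,1,1,,0,No rejection,A-TCMR,0
104347-2017-109,104347,2017,protocol,109,compatible,-,0,,0,,1,0,0,1,0,1,0,0,,0,Other,A-TCMR,0
105060-2021-360,105060,2021,protocol,360,compatible,-,0,0,0,0,2,1,0,0,0,0,0,0,,0,Other,A-TCMR,0
105192-2022-16,105192,2022,for-cause,16,incompatible,-,0,,1,0,3,1,0,2,0,0,0,0,,1,TMA,A-TCMR,0
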