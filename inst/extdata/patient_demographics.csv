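patient,sex,age_first_scan,age_last_scan,mean_interval,disease_duration_first,edss_first,edss_last,edss_annual_rate,scanner,n_mdeft,n_mprage_vdk
1,F,16.32,22.19,0.65,4.33,1.5,1,-0.087,Verio,0,10
2,F,29.93,35.24,0.48,NA,NA,NA,NA,Verio,1,12
3,F,31.72,36.78,0.56,12.42,2,4,0.435,Verio,1,10
4,F,21.43,25.09,0.52,2.75,1.5,1,-0.169,Verio,2,8
5,F,41.41,46.67,0.53,4.5,2,2,0.067,Verio,0,11
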