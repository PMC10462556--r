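category,phase,module,label,duration_mean_s,duration_sd_s,occ_mean,occ_sd,presence_p,role
S56,05,P05M02,Imaging (US),252,188,2,1.2,1,step
S56,06,P06M01,Planning,85,47,5,1.2,1,step
S56,07,P07M01,Trocars placement,157,87,3.6,0.5,1,step
S56,07,P07M02,Insufflation,NA,NA,1,0,1,step
S56,08a,P08aM01,Fat/adhesion dissection,90,0,0.2,0.4,0.2,step
S56,08a,P08aM02,Mobilization,548,43,0.6,0.9,0.4,step
S56,08a,P08aM03,Supply-duct isolation,400,370,5.6,8.8,0.6,step
S56,08a,P08aM05,Permanent occlusion,134,120,1.6,2,0.6,step
S56,08a,P08aM06,Supply-duct division,410,387,5.4,8.4,0.6,step
S56,10,P10M01,Region marking,176,86,1,0,1,step
S56,10,P10M02,Resection,1343,951,2.6,1.8,1,step
S56,11,P11M02,Leakage clean-up (intra-operative),222,172,6.4,3.3,1,fixed_leakage
S56,13,P13M02,Package,101,81,1,0,1,step
S56,13,P13M03,Removal,52,47,1,0.5,1,step
S56,13,P13M04,Leakage clean-up (wrap-up),223,220,3.4,1.7,1,step
S56,13,P13M05,Leak testing,100,17,1,1.4,0.4,step
S56,13,P13M06,Leak closure,252,120,3,1.2,1,step
S56,13,P13M07,Irrigation,0,0,0,0,0,step
S56,13,P13M08,Desufflation,NA,NA,NA,NA,1,untimed
S56,13,P13M09,Incision closing,NA,NA,NA,NA,1,untimed
S56,idle,IDLE,Idle time,193,67,NA,NA,1,fixed_idle
S78,05,P05M02,Imaging (US),1259,1491,3.4,1.3,1,step
S78,06,P06M01,Planning,181,146,7.8,2.9,1,step
S78,07,P07M01,Trocars placement,132,73,4,0.7,1,step
S78,07,P07M02,Insufflation,NA,NA,1,0,1,step
S78,08a,P08aM01,Fat/adhesion dissection,2692,0,0.6,1.3,0.2,step
S78,08a,P08aM02,Mobilization,191,10,0.4,0.5,0.4,step
S78,08a,P08aM03,Supply-duct isolation,0,0,0,0,0,step
S78,08a,P08aM05,Permanent occlusion,0,0,0,0,0,step
S78,08a,P08aM06,Supply-duct division,0,0,0,0,0,step
S78,10,P10M01,Region marking,197,85,1.2,0.4,1,step
S78,10,P10M02,Resection,1421,736,1.6,0.9,1,step
S78,11,P11M02,Leakage clean-up (intra-operative),291,190,7,4.4,1,fixed_leakage
S78,13,P13M02,Package,63,20,1,0,1,step
S78,13,P13M03,Removal,105,32,1.4,0.9,1,step
S78,13,P13M04,Leakage clean-up (wrap-up),225,222,4.8,3.3,1,step
S78,13,P13M05,Leak testing,99,75,1.2,1.6,0.6,step
S78,13,P13M06,Leak closure,218,144,2.4,2.9,0.6,step
S78,13,P13M07,Irrigation,98,9,0.8,0.8,0.6,step
S78,13,P13M08,Desufflation,NA,NA,NA,NA,1,untimed
S78,13,P13M09,Incision closing,NA,NA,NA,NA,1,untimed
S78,idle,IDLE,Idle time,931,1154,NA,NA,1,fixed_idle
S5GB,05,P05M02,Imaging (US),235,184,1,1,1,step
S5GB,06,P06M01,Planning,222,146,6,1.7,1,step
S5GB,07,P07M01,Trocars placement,170,40,4,0,1,step
S5GB,07,P07M02,Insufflation,NA,NA,1,0,1,step
S5GB,08a,P08aM01,Fat/adhesion dissection,209,0,0.7,1.1,0.33,step
S5GB,08a,P08aM02,Mobilization,855,414,4,1.7,1,step
S5GB,08a,P08aM03,Supply-duct isolation,150,111,1.33,0.6,1,step
S5GB,08a,P08aM05,Permanent occlusion,60,26,1.67,0.6,1,step
S5GB,08a,P08aM06,Supply-duct division,38,10,1.67,0.6,1,step
S5GB,10,P10M01,Region marking,259,93,1,0,1,step
S5GB,10,P10M02,Resection,1210,253,1.7,0.6,1,step
S5GB,11,P11M02,Leakage clean-up (intra-operative),347,291,8,7,1,fixed_leakage
S5GB,13,P13M02,Package,138,3,1.3,0.6,1,step
S5GB,13,P13M03,Removal,227,205,1.3,0.6,1,step
S5GB,13,P13M04,Leakage clean-up (wrap-up),128,72,2.7,0.6,1,step
S5GB,13,P13M05,Leak testing,75,70,0.7,0.6,0.66,step
S5GB,13,P13M06,Leak closure,438,340,1.7,0.6,1,step
S5GB,13,P13M07,Irrigation,0,0,0,0,0,step
S5GB,13,P13M08,Desufflation,NA,NA,NA,NA,1,untimed
S5GB,13,P13M09,Incision closing,NA,NA,NA,NA,1,untimed
S5GB,idle,IDLE,Idle time,322,51,NA,NA,1,fixed_idle
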