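name,units,value,min,max,status
q_sbv,m3,0.001,4e-04,0.0025,free
E_LVa,MPa/m3,300,80,900,free
E_RVa,MPa/m3,73.3,20,300,free
R_par,MPa.s/m3,10.7,2,60,free
R_LE_T,MPa.s/m3,1200,300,8000,free
R_BR_T,MPa.s/m3,3500,800,20000,free
R_AC_T,MPa.s/m3,7000,1500,40000,free
R_EC_T,MPa.s/m3,4200,1000,25000,free
R_MC_T,MPa.s/m3,4500,1000,25000,free
R_PC_T,MPa.s/m3,19000,4000,80000,free
R_TR_T,MPa.s/m3,200,50,2000,free
C_V,m3/MPa,0.5,0.1,2.5,free
E_LVb,MPa/m3,8,1,30,fixed
q_LV_un,m3,1e-05,0,5e-05,fixed
on_LV,fraction,0,0,1,fixed
du_LV,fraction,0.3,0.05,0.6,fixed
E_RVb,MPa/m3,4,1,30,fixed
q_RV_un,m3,1e-05,0,5e-05,fixed
on_RV,fraction,0,0,1,fixed
du_RV,fraction,0.3,0.05,0.6,fixed
E_LAa,MPa/m3,36,5,150,fixed
E_LAb,MPa/m3,12,2,60,fixed
q_LA_un,m3,5e-06,0,5e-05,fixed
on_LA,fraction,0.8,0,1,fixed
du_LA,fraction,0.17,0.05,0.5,fixed
E_RAa,MPa/m3,30,5,150,fixed
E_RAb,MPa/m3,10,2,60,fixed
q_RA_un,m3,5e-06,0,5e-05,fixed
on_RA,fraction,0.8,0,1,fixed
du_RA,fraction,0.17,0.05,0.5,fixed
R_trv,MPa.s/m3,0.3,0.05,5,fixed
R_puv,MPa.s/m3,0.6,0.05,5,fixed
R_miv,MPa.s/m3,0.3,0.05,5,fixed
R_aov,MPa.s/m3,0.8,0.05,5,fixed
k_valve,1/MPa,30000,1000,1e+06,fixed
C_par,m3/MPa,0.03,0.005,0.2,fixed
C_pvn,m3/MPa,0.15,0.02,1,fixed
R_pvn,MPa.s/m3,0.5,0.05,5,fixed
C_AO,m3/MPa,0.0113,0.002,0.1,fixed
C_CER,m3/MPa,0.002,2e-04,0.02,fixed
R_seg_CER,MPa.s/m3,30,5,200,fixed
R_seg_BR,MPa.s/m3,50,5,300,fixed
R_seg_LE,MPa.s/m3,30,5,300,fixed
R_seg_TR,MPa.s/m3,10,2,100,fixed
C_LE_T,m3/MPa,5e-04,5e-05,0.005,fixed
C_BR_T,m3/MPa,2e-04,2e-05,0.002,fixed
C_AC_T,m3/MPa,1e-04,1e-05,0.001,fixed
C_EC_T,m3/MPa,0.00015,1.5e-05,0.0015,fixed
C_MC_T,m3/MPa,0.00015,1.5e-05,0.0015,fixed
C_PC_T,m3/MPa,5e-05,5e-06,5e-04,fixed
C_TR_T,m3/MPa,0.001,1e-04,0.01,fixed
R_LE_V,MPa.s/m3,120,10,1000,fixed
R_BR_V,MPa.s/m3,350,10,3000,fixed
R_AC_V,MPa.s/m3,700,10,6000,fixed
R_EC_V,MPa.s/m3,420,10,4000,fixed
R_MC_V,MPa.s/m3,450,10,4000,fixed
R_PC_V,MPa.s/m3,1900,10,16000,fixed
R_TR_V,MPa.s/m3,20,2,200,fixed
f_vub,fraction,0.3,0.05,0.95,fixed
R_svc,MPa.s/m3,1,0.1,10,fixed
R_ivc,MPa.s/m3,0.8,0.1,10,fixed
period,s,1,0.3,2,fixed
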