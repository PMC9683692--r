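patient_id,name,value,cv_percent,sigma
template,max(q_la),NA,21.3,NA
template,min(q_la),NA,23.5,NA
template,max(q_lv),NA,12.6,NA
template,min(q_lv),NA,19.4,NA
template,max(q_ra),NA,10,NA
template,max(p_BR),NA,1.5,NA
template,min(p_BR),NA,4,NA
template,mean(p_BR),NA,2.75,NA
template,mean(v_LE_T),NA,30,NA
template,mean(v_BR_T),NA,30,NA
template,mean(v_PC_T),NA,8,NA
template,mean(v_EC_T),NA,8,NA
template,mean(v_MC_T),NA,8,NA
template,mean(v_AC_T),NA,8,NA
template,mean(v_TR_T),NA,50,NA
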