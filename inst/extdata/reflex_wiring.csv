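"target","kind","source","gain","sign","offset","phases","loadw","side","delay"
"SOL_l","F","SOL_l","sol_f_l",1,"0","ES,MS,PS",0,"l",0.02
"SOL_l","F","SOL_l","sol_f_ps_l",1,"0","PS",0,"l",0.02
"GAS_l","F","GAS_l","gas_f_l",1,"0","ES,MS,PS",0,"l",0.02
"GAS_l","L","GAS_l","gas_l_l",1,"gas_l_off_l","PS",0,"l",0.02
"VAS_l","F","VAS_l","vas_f_l",1,"0","ES,MS",0,"l",0.01
"VAS_l","C","","vas_c_l",1,"0","ES,MS",0,"l",0.005
"VAS_l","C","","vas_c_lp_l",1,"0","LP",0,"l",0.005
"TA_l","L","TA_l","ta_l_l",1,"ta_l_off_l","ES,MS,PS,SW,LP",0,"l",0.02
"TA_l","F","SOL_l","ta_sol_f_l",-1,"0","ES,MS,PS",0,"l",0.02
"TA_l","C","","ta_c_sw_l",1,"0","SW",0,"l",0.005
"HAM_l","PD","","ham_pd_l",1,"0","ES,MS",1,"l",0.005
"GLU_l","PD","","glu_pd_l",1,"0","ES,MS",1,"l",0.005
"IL_l","PD","","il_pd_l",-1,"0","ES,MS",1,"l",0.005
"IL_l","C","","il_c_ps_l",1,"0","PS",0,"l",0.005
"IL_l","C","","il_c_sw_l",1,"0","SW",0,"l",0.005
"IL_l","L","IL_l","il_l_l",1,"il_l_off_l","PS,SW",0,"l",0.005
"IL_l","L","HAM_l","il_ham_l_l",-1,"0.85","SW",0,"l",0.005
"GLU_l","C","","glu_c_sw_l",1,"0","SW",0,"l",0.005
"GLU_l","C","","glu_c_lp_l",1,"0","LP",0,"l",0.005
"HAM_l","C","","ham_c_sw_l",1,"0","SW",0,"l",0.005
"HAM_l","F","HAM_l","ham_f_lp_l",1,"0","LP",0,"l",0.005
"GLU_l","F","GLU_l","glu_f_lp_l",1,"0","LP",0,"l",0.005
"SOL_r","F","SOL_r","sol_f_r",1,"0","ES,MS,PS",0,"r",0.02
"SOL_r","F","SOL_r","sol_f_ps_r",1,"0","PS",0,"r",0.02
"GAS_r","F","GAS_r","gas_f_r",1,"0","ES,MS,PS",0,"r",0.02
"GAS_r","L","GAS_r","gas_l_r",1,"gas_l_off_r","PS",0,"r",0.02
"VAS_r","F","VAS_r","vas_f_r",1,"0","ES,MS",0,"r",0.01
"VAS_r","C","","vas_c_r",1,"0","ES,MS",0,"r",0.005
"VAS_r","C","","vas_c_lp_r",1,"0","LP",0,"r",0.005
"TA_r","L","TA_r","ta_l_r",1,"ta_l_off_r","ES,MS,PS,SW,LP",0,"r",0.02
"TA_r","F","SOL_r","ta_sol_f_r",-1,"0","ES,MS,PS",0,"r",0.02
"TA_r","C","","ta_c_sw_r",1,"0","SW",0,"r",0.005
"HAM_r","PD","","ham_pd_r",1,"0","ES,MS",1,"r",0.005
"GLU_r","PD","","glu_pd_r",1,"0","ES,MS",1,"r",0.005
"IL_r","PD","","il_pd_r",-1,"0","ES,MS",1,"r",0.005
"IL_r","C","","il_c_ps_r",1,"0","PS",0,"r",0.005
"IL_r","C","","il_c_sw_r",1,"0","SW",0,"r",0.005
"IL_r","L","IL_r","il_l_r",1,"il_l_off_r","PS,SW",0,"r",0.005
"IL_r","L","HAM_r","il_ham_l_r",-1,"0.85","SW",0,"r",0.005
"GLU_r","C","","glu_c_sw_r",1,"0","SW",0,"r",0.005
"GLU_r","C","","glu_c_lp_r",1,"0","LP",0,"r",0.005
"HAM_r","C","","ham_c_sw_r",1,"0","SW",0,"r",0.005
"HAM_r","F","HAM_r","ham_f_lp_r",1,"0","LP",0,"r",0.005
"GLU_r","F","GLU_r","glu_f_lp_r",1,"0","LP",0,"r",0.005
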