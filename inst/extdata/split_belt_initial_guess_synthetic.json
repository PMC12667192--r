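{"description":"Synthetic stand-in produced by this package's reduced CMA-ES protocol (not an external source)","spinal":{"sol_f_l":0.03460716,"sol_f_ps_l":0.12236974,"gas_f_l":0.0037811,"gas_l_l":0.39355334,"gas_l_off_l":0.65082179,"vas_f_l":0.23348936,"vas_c_l":0.23865049,"vas_c_lp_l":0,"ta_l_l":0.23623377,"ta_l_off_l":0.73698049,"ta_sol_f_l":0.16438059,"ta_c_sw_l":0.32245019,"ham_pd_l":0.59996176,"glu_pd_l":1.37561349,"il_pd_l":1.21806385,"il_c_ps_l":0.3545799,"il_c_sw_l":0.26281307,"il_l_l":2.14707819,"il_l_off_l":0.4,"il_ham_l_l":0.07599513,"glu_c_sw_l":0.09429753,"glu_c_lp_l":0.07293323,"ham_c_sw_l":0,"ham_f_lp_l":1.2,"glu_f_lp_l":0.9,"pd_kp_l":3.8337149,"pd_kd_l":1.13136226,"pd_ref_l":-0.13385817,"load_es_ms_l":0.02,"load_ps_sw_l":0.02,"sw_lp_angle_l":0.17758228,"sol_f_r":0.23732588,"sol_f_ps_r":0.0898929,"gas_f_r":0.1237694,"gas_l_r":0.05602172,"gas_l_off_r":0.54684526,"vas_f_r":0.30153173,"vas_c_r":0.19005997,"vas_c_lp_r":0.13099667,"ta_l_r":1.12606677,"ta_l_off_r":0.4,"ta_sol_f_r":0.41368021,"ta_c_sw_r":0.37075945,"ham_pd_r":1.06725461,"glu_pd_r":0.85380081,"il_pd_r":0.31608055,"il_c_ps_r":0.29853663,"il_c_sw_r":2.71750492,"il_l_r":0.70883051,"il_l_off_r":0.4,"il_ham_l_r":0.08053582,"glu_c_sw_r":0.05490224,"glu_c_lp_r":0.23009364,"ham_c_sw_r":0.08405607,"ham_f_lp_r":0.72301174,"glu_f_lp_r":0.02183304,"pd_kp_r":6.10641612,"pd_kd_r":3.49677471,"pd_ref_r":-0.02105529,"load_es_ms_r":0.02514386,"load_ps_sw_r":0.12600915,"sw_lp_angle_r":0.43071727},"t_left":0.75,"t_right":0.75,"alpha":0.002,"beta":0.02}
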