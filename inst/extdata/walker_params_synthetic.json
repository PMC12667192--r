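{"description":"Synthetic stand-in produced by this package's reduced CMA-ES protocol (not an external source)","spinal":{"sol_f_l":0.01627615,"sol_f_ps_l":0.14708057,"gas_f_l":0.01131054,"gas_l_l":0.41273272,"gas_l_off_l":0.4,"vas_f_l":0.19462087,"vas_c_l":0.27183845,"vas_c_lp_l":0.00902739,"ta_l_l":0.30067202,"ta_l_off_l":0.54816235,"ta_sol_f_l":0.10005313,"ta_c_sw_l":0.43300323,"ham_pd_l":0.62753334,"glu_pd_l":1.41688564,"il_pd_l":1.19803793,"il_c_ps_l":0.32985267,"il_c_sw_l":0.23563337,"il_l_l":1.7708849,"il_l_off_l":0.44585992,"il_ham_l_l":0.07384922,"glu_c_sw_l":0.09507521,"glu_c_lp_l":0.05222204,"ham_c_sw_l":0,"ham_f_lp_l":1.23221533,"glu_f_lp_l":0.59568692,"pd_kp_l":5.30905296,"pd_kd_l":1.5957307,"pd_ref_l":-0.14924641,"load_es_ms_l":0.04855595,"load_ps_sw_l":0.04424336,"sw_lp_angle_l":0.18080111,"sol_f_r":0.25696198,"sol_f_ps_r":0.06484754,"gas_f_r":0.1009302,"gas_l_r":0.04808916,"gas_l_off_r":0.4,"vas_f_r":0.29895845,"vas_c_r":0.16119146,"vas_c_lp_r":0.09465068,"ta_l_r":1.40507525,"ta_l_off_r":0.4,"ta_sol_f_r":0.42181428,"ta_c_sw_r":0.47352205,"ham_pd_r":1.0955489,"glu_pd_r":0.67202191,"il_pd_r":0.3429905,"il_c_ps_r":0.30528086,"il_c_sw_r":2.47672184,"il_l_r":0.83945772,"il_l_off_r":0.4,"il_ham_l_r":0.07349175,"glu_c_sw_r":0.06680811,"glu_c_lp_r":0.20239679,"ham_c_sw_r":0.06180005,"ham_f_lp_r":0.89322089,"glu_f_lp_r":0.02159352,"pd_kp_r":5.57338545,"pd_kd_r":5.0538085,"pd_ref_r":-0.02624395,"load_es_ms_r":0.02228489,"load_ps_sw_r":0.15549468,"sw_lp_angle_r":0.48244423},"t_left":0.54173313,"t_right":0.62037896,"alpha":0.013501387015,"beta":0.016466007394}
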