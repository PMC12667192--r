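{"description":"Synthetic symmetric tied-belt walker with packaged limit-cycle initial state; produced by this package's reduced optimization protocol","spinal":{"sol_f_l":0.08684255,"sol_f_ps_l":0.41687068,"gas_f_l":1.22212876,"gas_l_l":0.37005748,"gas_l_off_l":0.75998607,"vas_f_l":0.5838359,"vas_c_l":0.11429226,"vas_c_lp_l":0.06492757,"ta_l_l":1.15020937,"ta_l_off_l":0.4,"ta_sol_f_l":0.23069439,"ta_c_sw_l":0.53549051,"ham_pd_l":0.70699197,"glu_pd_l":0.81015617,"il_pd_l":0.66675632,"il_c_ps_l":0.30883057,"il_c_sw_l":0.45399597,"il_l_l":2.9569265,"il_l_off_l":0.4,"il_ham_l_l":0.01182197,"glu_c_sw_l":0.01854053,"glu_c_lp_l":0.07218373,"ham_c_sw_l":0.05290924,"ham_f_lp_l":0.58961136,"glu_f_lp_l":0.49024119,"pd_kp_l":10.27785734,"pd_kd_l":4.05310534,"pd_ref_l":-0.04325456,"load_es_ms_l":0.10207659,"load_ps_sw_l":0.08178521,"sw_lp_angle_l":0.40629732,"sol_f_r":0.08684255,"sol_f_ps_r":0.41687068,"gas_f_r":1.22212876,"gas_l_r":0.37005748,"gas_l_off_r":0.75998607,"vas_f_r":0.5838359,"vas_c_r":0.11429226,"vas_c_lp_r":0.06492757,"ta_l_r":1.15020937,"ta_l_off_r":0.4,"ta_sol_f_r":0.23069439,"ta_c_sw_r":0.53549051,"ham_pd_r":0.70699197,"glu_pd_r":0.81015617,"il_pd_r":0.66675632,"il_c_ps_r":0.30883057,"il_c_sw_r":0.45399597,"il_l_r":2.9569265,"il_l_off_r":0.4,"il_ham_l_r":0.01182197,"glu_c_sw_r":0.01854053,"glu_c_lp_r":0.07218373,"ham_c_sw_r":0.05290924,"ham_f_lp_r":0.58961136,"glu_f_lp_r":0.49024119,"pd_kp_r":10.27785734,"pd_kd_r":4.05310534,"pd_ref_r":-0.04325456,"load_es_ms_r":0.10207659,"load_ps_sw_r":0.08178521,"sw_lp_angle_r":0.40629732},"t_left":0.68,"t_right":0.68,"alpha":0.002,"beta":0.02,"init":{"q":[0,0.9364483875,-0.0324085697,-0.0226620707,0.6751630288,0.1254730544,0.1045368539,-0.0211721613,-0.050375898],"qd":[-0.2549041568,-0.0010511945,-0.513687062,2.9435107729,-1.6345747555,0.7518597045,0.1467136363,0.8575391546,-0.6315492333],"a":[0.0629090133,0.0298359576,0.9999999963,0.012072845,0.0605101793,0.012888427,0.9999931638,0.3624280849,0.4125988122,0.1193897105,0.1935365748,0.1371363101,0.0108761005,0.6064711973],"lce":[0.8274272793,0.9787210127,0.9817596464,1.2189677614,0.8441121493,1.1006024136,0.798404295,1.0633444337,1.0306756879,0.9398916335,0.8544313252,0.9125354865,0.9108642024,0.9175013328],"phase":["SW","MS"],"elapsed":[0.8668,0.2362]}}
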