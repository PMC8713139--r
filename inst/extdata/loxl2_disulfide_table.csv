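domain,bond_id,work_kJ_mol,E_cal_mV,E_corr_mV,nernst_consistent
SRCR1,Cys84-Cys148,37.20,-201.11,-348.67,FALSE
SRCR1,Cys97-Cys158,46.58,-249.13,-420.70,FALSE
SRCR1,Cys128-Cys138,36.22,-191.67,-334.51,FALSE
SRCR2,Cys218-Cys291,36.68,-192.07,-335.11,FALSE
SRCR2,Cys231-Cys301,49.78,-260.67,-438.00,FALSE
SRCR2,Cys265-Cys275,39.19,-205.22,-354.82,FALSE
SRCR3,Cys351-Cys414,28.59,-148.16,-269.24,TRUE
SRCR3,Cys364-Cys424,47.06,-243.87,-412.81,TRUE
SRCR3,Cys395-Cys405,37.63,-195.00,-339.51,TRUE
SRCR4,Cys464-Cys530,21.63,-112.09,-215.13,TRUE
SRCR4,Cys477-Cys543,28.66,-148.52,-269.78,TRUE
SRCR4,Cys511-Cys521,48.71,-252.84,-425.63,FALSE
Catalytic,Cys573-Cys625,18.08,-93.69,-187.54,TRUE
Catalytic,Cys579-Cys695,28.87,-149.61,-271.41,TRUE
Catalytic,Cys657-Cys673,17.36,-89.96,-181.94,TRUE
Catalytic,Cys663-Cys685,32.31,-167.44,-298.15,TRUE
Catalytic,Cys732-Cys746,43.58,-225.84,-385.76,TRUE
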