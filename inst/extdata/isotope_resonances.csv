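isotope,b_coh_far_fm,sigma_inc_barn,sigma_abs_2200_barn,E_r_meV,Gamma_meV,Gamma_n_meV,R_fm
C,6.6460,0.001,0.0035,NA,NA,NA,NA
D,6.671,2.05,0.000519,NA,NA,NA,NA
N,9.36,0.50,1.90,NA,NA,NA,NA
O,5.803,0.0008,0.00019,NA,NA,NA,NA
S,2.847,0.007,0.53,NA,NA,NA,NA
Cd113,6.7046,0.3,NA,178,113.97419,0.474190,6.7046
Sm149,-19.2,137,NA,97.3,61.033,0.533,8.0
Eu151,6.1,3.1,NA,321,95.9,0.9,7.2
Gd157,-1.14,394,NA,31.4,106.87,0.47,7.8
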