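table,field,group,stat,value
table2,stress_1g_bf,all,mean,7.323
table2,stress_1g_be,all,mean,84.70
table2,stress_2g_bf,all,mean,7.17
table2,stress_2g_ef,all,mean,43.10
table2,stress_2g_be,all,mean,108.41
table2,stress_2g_ee,all,mean,28.89
table3,strain_1g_bf,all,mean,0.062
table3,strain_1g_be,all,mean,0.434
table3,strain_2g_bf,all,mean,0.048
table3,strain_2g_ef,all,mean,0.425
table3,strain_2g_be,all,mean,0.606
table3,strain_2g_ee,all,mean,0.164
table6,delta_ef,1,mean,1.34
table6,delta_ef,1,sd,3.9
table6,wt,1,mean,0.45
table6,wt,1,sd,0.08
table6,ccur,1,mean,0.48
table6,ccur,1,sd,0.07
table6,lcur,1,mean,1.40
table6,lcur,1,sd,0.48
table6,edv,1,mean,302.3
table6,edv,1,sd,93.7
table6,stress,1,mean,82.9
table6,stress,1,sd,27.5
table6,strain,1,mean,0.59
table6,strain,1,sd,0.09
table6,delta_ef,2,mean,-11.1
table6,delta_ef,2,sd,4.4
table6,wt,2,mean,0.53
table6,wt,2,sd,0.14
table6,ccur,2,mean,0.57
table6,ccur,2,sd,0.34
table6,lcur,2,mean,1.13
table6,lcur,2,sd,0.38
table6,edv,2,mean,387.4
table6,edv,2,sd,154.8
table6,stress,2,mean,133.9
table6,stress,2,sd,31.4
table6,strain,2,mean,0.62
table6,strain,2,sd,0.14
table6,wt,all,corr_r,-0.313
table6,wt,all,corr_p,0.239
table6,ccur,all,corr_r,0.012
table6,ccur,all,corr_p,0.965
table6,lcur,all,corr_r,0.433
table6,lcur,all,corr_p,0.094
table6,edv,all,corr_r,-0.60
table6,edv,all,corr_p,0.015
table6,stress,all,corr_r,-0.608
table6,stress,all,corr_p,0.012
table6,strain,all,corr_r,0.033
table6,strain,all,corr_p,0.903
table1,age,all,mean,40.4
table1,age,all,sd,16.6
table1,pre_edv,all,mean,387.7
table1,pre_edv,all,sd,154.8
table1,pre_esv,all,mean,228.4
table1,pre_esv,all,sd,121.3
table1,pre_ef,all,mean,42.7
table1,pre_ef,all,sd,8.0
table1,post_edv,all,mean,278.0
table1,post_edv,all,sd,85.8
table1,post_esv,all,mean,193.8
table1,post_esv,all,sd,82.6
table1,post_ef,all,mean,31.4
table1,post_ef,all,sd,9.9
table1,delta_ef,all,mean,-11.1
table1,delta_ef,all,sd,4.4
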