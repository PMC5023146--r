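name,file,md5
table1_demographics,table1_demographics.csv,f1b5f6cc1e340f46e445238a61755367
table2_stress,table2_stress.csv,9ecbd23606a6c2043afaf7f3a09bfd4c
table3_strain,table3_strain.csv,3d9b3ba6213c618027f2893f2cf56260
table4_wt_curvature,table4_wt_curvature.csv,0110ac9736ca39d6b7046bf7efed3569
table6_be_metrics,table6_be_metrics.csv,9f85913bcccc60a6f208c8efeb4659d8
printed_aggregates,printed_aggregates.csv,a7e0f9b7d095593b277241aeda666977
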