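parameter,units,val_1g_bf,val_1g_be,val_2g_bf,val_2g_ef,val_2g_be,val_2g_ee
wall_thickness,cm,0.564,0.505,0.575,0.519,0.491,0.525
circumferential_curvature,1/cm,0.630,0.514,0.638,0.516,0.524,0.618
longitudinal_curvature,1/cm,1.216,1.186,1.193,1.155,1.263,1.389
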