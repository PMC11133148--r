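term,chi2,chi2_df,cfi,rmsea,srmr
intercept,-23.94201,3.28519,-0.53129,0.13285,0.05279
est_mlr,6.72418,0.45189,-0.21041,0.01536,NA
est_dwls,5.84976,-0.68404,0.19662,-0.03062,0.03774
est_wlsmv,-4.68805,-0.27096,0.06079,-0.00865,NA
indicators,11.08965,-0.04753,0.04016,-0.00235,0.00278
options,-7.16670,-0.35058,0.12387,-0.00896,-0.00963
options_sq,0.72250,0.03496,-0.00936,0.00098,0.00084
asymmetric,-0.27294,0.02331,-0.04904,-0.00024,-0.00115
loading,-25.73792,-3.58376,4.12967,-0.08865,0.02653
loading_sq,20.41717,2.96247,-2.75074,0.05766,-0.09506
size,0.00906,0.45022,2.27580,-0.12606,-0.05619
size_sq,1.20211,-0.15723,-0.82698,0.04331,0.01882
factors,-12.26618,-0.19792,-0.32211,-0.00594,0.01323
est_mlr_x_indicators,-0.49485,-0.01090,0.00247,-0.00041,NA
est_mlr_x_options,0.17085,0.00216,0.00384,0.00005,NA
est_mlr_x_options_sq,-0.02131,-0.00052,-0.00024,-0.00001,NA
est_mlr_x_asymmetric,-2.71568,-0.08311,-0.00135,-0.00225,NA
est_mlr_x_loading,-7.76460,-0.99175,0.45378,-0.03246,NA
est_mlr_x_loading_sq,-2.61117,0.42949,-0.31994,0.01556,NA
est_mlr_x_size,-3.93101,-0.26550,0.09707,-0.00768,NA
est_mlr_x_size_sq,1.45709,0.09907,-0.03794,0.00311,NA
est_mlr_x_factors,2.71283,0.11781,-0.00868,0.00304,NA
est_dwls_x_indicators,-2.43747,0.00544,0.00158,-0.00038,-0.00022
est_dwls_x_options,-0.39327,-0.02550,-0.00440,-0.00033,-0.00758
est_dwls_x_options_sq,0.02110,0.00195,0.00034,0.00003,0.00058
est_dwls_x_asymmetric,-3.01669,-0.09613,0.00452,-0.00244,0.00140
est_dwls_x_loading,-41.99689,-1.36226,-0.30944,-0.05998,-0.00280
est_dwls_x_loading_sq,16.73726,0.48895,0.18350,0.02118,-0.00311
est_dwls_x_size,-2.10846,-0.11430,-0.11629,0.02896,-0.02165
est_dwls_x_size_sq,0.75628,0.04419,0.04250,-0.00982,0.00756
est_dwls_x_factors,16.86537,0.64662,-0.01075,0.02281,0.00330
est_wlsmv_x_indicators,-0.60239,-0.00413,0.00097,-0.00029,NA
est_wlsmv_x_options,0.63654,0.01440,-0.00270,0.00054,NA
est_wlsmv_x_options_sq,-0.05539,-0.00115,0.00022,-0.00004,NA
est_wlsmv_x_asymmetric,-2.91980,-0.09484,0.00368,-0.00256,NA
est_wlsmv_x_loading,10.29574,0.24493,-0.06415,0.00577,NA
est_wlsmv_x_loading_sq,-15.70961,-0.45035,0.03405,-0.01194,NA
est_wlsmv_x_size,3.01133,0.05021,-0.04314,0.00682,NA
est_wlsmv_x_size_sq,-1.16888,-0.01938,0.01545,-0.00250,NA
est_wlsmv_x_factors,3.90897,0.15706,-0.00697,0.00452,NA
indicators_x_options,-0.25997,-0.00776,0.00002,-0.00033,-0.00019
indicators_x_options_sq,0.02789,0.00081,-0.00003,0.00004,0.00002
indicators_x_asymmetric,0.17890,0.00040,0.00034,0.00002,0.00003
indicators_x_loading,-4.80064,-0.04388,-0.10488,-0.00698,-0.00316
indicators_x_loading_sq,3.83154,0.04484,0.07017,0.00652,0.00190
indicators_x_size,-1.04664,0.00016,-0.01404,0.00655,-0.00160
indicators_x_size_sq,0.38895,0.00157,0.00500,-0.00224,0.00058
indicators_x_factors,0.64889,-0.01164,0.00234,-0.00030,0.00003
options_x_asymmetric,0.47743,0.01356,-0.00319,0.00043,0.00061
options_x_loading,22.43204,1.53987,-0.33800,0.04504,0.01794
options_x_loading_sq,-19.13312,-1.33866,0.23297,-0.03818,-0.01639
options_x_size,2.42094,-0.20111,-0.00951,-0.00561,0.01125
options_x_size_sq,-1.16974,0.07428,0.00109,0.00208,-0.00388
options_x_factors,1.18404,0.04887,0.00555,0.00098,0.00068
options_sq_x_asymmetric,-0.04690,-0.00122,0.00031,-0.00005,-0.00006
options_sq_x_loading,-2.12451,-0.14685,0.02682,-0.00451,-0.00166
options_sq_x_loading_sq,1.79085,0.12730,-0.01863,0.00381,0.00151
options_sq_x_size,-0.40475,0.01424,0.00006,0.00030,-0.00097
options_sq_x_size_sq,0.17973,-0.00524,0.00020,-0.00011,0.00034
options_sq_x_factors,-0.10687,-0.00463,-0.00039,-0.00010,-0.00005
asymmetric_x_loading,3.71952,0.27558,0.11280,0.01327,0.00844
asymmetric_x_loading_sq,-1.17710,-0.18396,-0.07174,-0.00937,-0.00713
asymmetric_x_size,0.29781,-0.00253,0.02437,-0.00219,-0.00393
asymmetric_x_size_sq,-0.16484,-0.00346,-0.00870,0.00072,0.00138
asymmetric_x_factors,-0.81043,-0.03425,-0.00208,-0.00101,-0.00028
loading_x_size,16.43214,0.03858,-5.87140,0.01187,-0.04098
loading_x_size_sq,-8.22119,-0.08583,2.14448,-0.00411,0.01586
loading_x_factors,1.82103,0.21559,0.65988,0.02703,-0.01793
loading_sq_x_size,-15.03742,-0.14310,3.87122,0.00022,0.06458
loading_sq_x_size_sq,7.54665,0.12608,-1.41187,0.00015,-0.02336
loading_sq_x_factors,5.02726,0.03351,-0.43878,-0.01413,0.04983
size_x_factors,0.39375,0.08076,0.09529,-0.00988,-0.02326
size_sq_x_factors,-0.26943,-0.03848,-0.03378,0.00320,0.00784
factors_x_correlated,-2.51728,-0.05765,0.00487,-0.00223,-0.00481
r_squared,0.970,0.810,0.902,0.903,0.963
n_cells,1296,1296,1296,1296,648
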