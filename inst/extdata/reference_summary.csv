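technique,theta,metric,mean,sd,side
conventional,NA,proximal_area,2370,546,NA
oblique,NA,proximal_area,1964,454,NA
hybrid_3_1,NA,proximal_area,1962,484,NA
hybrid_2_1,NA,proximal_area,1962,484,NA
conventional,12,distal_area,1962,417,NA
oblique,12,distal_area,1741,375,NA
hybrid_3_1,12,distal_area,1595,343,NA
hybrid_2_1,12,distal_area,1382,364,NA
conventional,15,distal_area,1844,399,NA
oblique,15,distal_area,1725,367,NA
hybrid_3_1,15,distal_area,1558,335,NA
hybrid_2_1,15,distal_area,1336,277,NA
conventional,18,distal_area,1786,379,NA
oblique,18,distal_area,1709,360,NA
hybrid_3_1,18,distal_area,1536,335,NA
hybrid_2_1,18,distal_area,1293,277,NA
conventional,12,nonoverlap,458,153,lateral
oblique,12,nonoverlap,190,88,lateral
hybrid_3_1,12,nonoverlap,101,46,medial
hybrid_2_1,12,nonoverlap,102,39,medial
conventional,15,nonoverlap,527,176,lateral
oblique,15,nonoverlap,242,108,lateral
hybrid_3_1,15,nonoverlap,119,42,medial
hybrid_2_1,15,nonoverlap,112,39,medial
conventional,18,nonoverlap,585,196,lateral
oblique,18,nonoverlap,287,130,lateral
hybrid_3_1,18,nonoverlap,134,48,medial
hybrid_2_1,18,nonoverlap,119,34,medial
conventional,12,wedge_volume,13558,6075,NA
oblique,12,wedge_volume,11742,4433,NA
hybrid_3_1,12,wedge_volume,7130,2753,NA
hybrid_2_1,12,wedge_volume,5281,2253,NA
conventional,15,wedge_volume,17055,6620,NA
oblique,15,wedge_volume,14720,5561,NA
hybrid_3_1,15,wedge_volume,8683,3456,NA
hybrid_2_1,15,wedge_volume,6251,2433,NA
conventional,18,wedge_volume,19924,7679,NA
oblique,18,wedge_volume,17719,6696,NA
hybrid_3_1,18,wedge_volume,10416,4334,NA
hybrid_2_1,18,wedge_volume,6866,3497,NA
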