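variable_id,species,max_diff,p_gxe,stars_gxe,p_e,stars_e
FH_LENGTH,timothy,-1921,0.96,,,**
FH_LENGTH,meadow_fescue,763,0.65,,0.67,
FH_LENGTH,festulolium,1006,,**,0.71,
FH_LENGTH,tall_fescue,1001,0.24,,0.22,
FH_LENGTH,red_clover,1128,,**,0.64,
FH_COLD5,timothy,977,0.90,,0.87,
FH_COLD5,meadow_fescue,-1028,0.62,,,***
FH_COLD5,festulolium,-1560,,**,0.11,
FH_COLD5,tall_fescue,-1088,0.80,,,**
FH_COLD5,red_clover,1239,0.37,,0.62,
FH_RAIN,timothy,-1904,0.86,,,*
FH_RAIN,meadow_fescue,1536,1.00,,,***
FH_RAIN,festulolium,2155,0.21,,,****
FH_RAIN,tall_fescue,1142,0.74,,,**
FH_RAIN,red_clover,1011,0.27,,0.76,
WP_WARM0_RATE,timothy,2100,0.53,,,***
WP_WARM0_RATE,meadow_fescue,2638,0.43,,,****
WP_WARM0_RATE,festulolium,2426,0.17,,,****
WP_WARM0_RATE,tall_fescue,2584,0.27,,,****
WP_WARM0_RATE,red_clover,2114,,*,,***
WP_STRESS15,timothy,-1287,0.25,,,****
WP_STRESS15,meadow_fescue,-2159,0.29,,,****
WP_STRESS15,festulolium,-1997,0.15,,,****
WP_STRESS15,tall_fescue,-1874,0.31,,,****
WP_STRESS15,red_clover,1145,0.40,,0.21,
GP_TSUM5,timothy,1870,0.81,,,****
GP_TSUM5,meadow_fescue,-1067,0.82,,,**
GP_TSUM5,festulolium,3367,,**,,****
GP_TSUM5,tall_fescue,2203,,***,,****
GP_TSUM5,red_clover,2481,0.13,,,****
GP_TSUM_RATE,timothy,1702,0.47,,,**
GP_TSUM_RATE,meadow_fescue,-1026,0.15,,,*
GP_TSUM_RATE,festulolium,579,0.15,,0.13,
GP_TSUM_RATE,tall_fescue,589,0.11,,0.91,
GP_TSUM_RATE,red_clover,2747,0.60,,,****
GP_HOT28,timothy,2756,0.97,,,***
GP_HOT28,meadow_fescue,1236,0.51,,0.42,
GP_HOT28,festulolium,1197,,***,0.39,
GP_HOT28,tall_fescue,755,0.04,,0.33,
GP_HOT28,red_clover,459,0.20,,,****
GP_HOT25_CUT1,timothy,-1503,0.31,,,***
GP_HOT25_CUT1,meadow_fescue,-1355,0.14,,0.22,
GP_HOT25_CUT1,festulolium,946,,**,,***
GP_HOT25_CUT1,tall_fescue,-628,0.30,,0.23,
GP_HOT25_CUT1,red_clover,877,0.30,,0.50,
GP_HOT25_CUT2,timothy,1554,0.50,,,**
GP_HOT25_CUT2,meadow_fescue,-1354,,**,,**
GP_HOT25_CUT2,festulolium,-831,,***,0.72,
GP_HOT25_CUT2,tall_fescue,-533,0.17,,0.94,
GP_HOT25_CUT2,red_clover,2542,,*,,**
GP_POSTCUT_TSUM7,timothy,-3141,,*,0.39,
GP_POSTCUT_TSUM7,meadow_fescue,-1355,0.97,,,**
GP_POSTCUT_TSUM7,festulolium,-1770,0.12,,,***
GP_POSTCUT_TSUM7,tall_fescue,-1750,0.95,,,****
GP_POSTCUT_TSUM7,red_clover,-1029,,*,0.43,
GP_RAIN_CUT1,timothy,-967,0.63,,0.97,
GP_RAIN_CUT1,meadow_fescue,757,0.97,,0.65,
GP_RAIN_CUT1,festulolium,-3049,,****,,***
GP_RAIN_CUT1,tall_fescue,291,0.31,,0.77,
GP_RAIN_CUT1,red_clover,655,0.11,,0.42,
GP_RAIN_CUT2,timothy,-1609,0.71,,0.40,
GP_RAIN_CUT2,meadow_fescue,895,0.36,,0.27,
GP_RAIN_CUT2,festulolium,-1668,,****,0.68,
GP_RAIN_CUT2,tall_fescue,-592,0.39,,0.89,
GP_RAIN_CUT2,red_clover,1253,0.26,,0.45,
GP_POSTCUT_RAIN14,timothy,-1516,0.51,,0.74,
GP_POSTCUT_RAIN14,meadow_fescue,1229,0.49,,0.21,
GP_POSTCUT_RAIN14,festulolium,756,0.11,,0.32,
GP_POSTCUT_RAIN14,tall_fescue,350,0.94,,0.56,
GP_POSTCUT_RAIN14,red_clover,1013,0.32,,0.16,
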