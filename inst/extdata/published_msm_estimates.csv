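term,submodel,coef,se,ratio,ci_lo,ci_hi
intercept,long_term,1.5854,0.0681,4.88,4.27,5.58
age_18_29,long_term,0.0117,0.0580,1.01,0.90,1.13
age_30_39,long_term,0.4088,0.0553,1.50,1.35,1.68
age_40_49,long_term,1.0181,0.0594,2.77,2.46,3.11
age_50_59,long_term,1.5998,0.0576,4.95,4.42,5.54
age_60_69,long_term,2.0480,0.0571,7.75,6.93,8.67
age_70_79,long_term,2.5912,0.0603,13.35,11.86,15.02
age_80_plus,long_term,3.4683,0.0721,32.08,27.86,36.95
sex_female,long_term,-0.0053,0.0143,0.99,0.97,1.02
race_black,long_term,0.3023,0.0164,1.35,1.31,1.40
race_asian,long_term,-0.6768,0.0301,0.51,0.48,0.54
race_american_indian,long_term,0.4665,0.0611,1.59,1.42,1.80
race_nhpi,long_term,-0.3154,0.0648,0.73,0.64,0.83
race_other,long_term,-0.5854,0.0640,0.56,0.49,0.63
hispanic_yes,long_term,-0.5295,0.0179,0.59,0.57,0.61
disease_hypertension,long_term,-1.2989,0.0263,0.27,0.26,0.29
disease_gn_cystic,long_term,-1.3087,0.0231,0.27,0.26,0.28
disease_other,long_term,-1.7385,0.0267,0.18,0.17,0.18
liu_index,long_term,0.1231,0.0039,1.13,1.12,1.14
inability_ambulate_yes,long_term,0.0712,0.0405,1.07,0.99,1.16
inability_transfer_yes,long_term,-0.1823,0.0548,0.83,0.75,0.93
needs_assistance_yes,long_term,-0.1539,0.0287,0.86,0.81,0.91
inst_nursing_home,long_term,-0.5866,0.0323,0.56,0.52,0.59
inst_assisted_living,long_term,-0.1325,0.1220,0.88,0.69,1.11
inst_other,long_term,-0.5200,0.0770,0.59,0.51,0.69
alcohol_yes,long_term,-0.0442,0.0337,0.96,0.90,1.02
tobacco_yes,long_term,0.3240,0.0209,1.38,1.33,1.44
drug_yes,long_term,-0.0884,0.0300,0.92,0.86,0.97
amputation_yes,long_term,0.0273,0.0604,1.03,0.91,1.16
toxic_nephropathy_yes,long_term,-0.5349,0.0625,0.59,0.52,0.66
peritoneal,long_term,0.1485,0.0228,1.16,1.11,1.21
transplant,long_term,-1.2711,0.0215,0.28,0.27,0.29
employment_employed,long_term,-0.0940,0.0211,0.91,0.87,0.95
employment_retired_age,long_term,0.4181,0.0312,1.52,1.43,1.61
employment_retired_disabled,long_term,0.3781,0.0197,1.46,1.40,1.52
employment_other,long_term,-0.0509,0.0277,0.95,0.90,1.00
ins_medicaid_only,long_term,0.0227,0.0230,1.02,0.98,1.07
ins_medicare_only,long_term,0.7411,0.0291,2.10,1.98,2.22
ins_dva_plus,long_term,0.4361,0.0696,1.55,1.35,1.77
ins_medicare_employer,long_term,0.7825,0.0351,2.19,2.04,2.34
ins_medicare_medicaid,long_term,0.8263,0.0329,2.29,2.14,2.44
ins_multiple_otherwise,long_term,1.0009,0.0388,2.72,2.52,2.94
ins_other,long_term,-0.0147,0.0239,0.98,0.94,1.03
ins_none,long_term,-0.1300,0.0221,0.88,0.84,0.92
rural_large,long_term,0.1236,0.0211,1.13,1.09,1.18
rural_small,long_term,0.1479,0.0316,1.16,1.09,1.23
rural_isolated,long_term,0.1316,0.0424,1.14,1.05,1.24
region_south,long_term,0.1842,0.0160,1.20,1.17,1.24
region_midwest,long_term,0.0829,0.0168,1.09,1.05,1.12
region_northeast,long_term,0.1376,0.0190,1.15,1.10,1.19
age_18_29,short_term,-0.2226,0.0390,0.80,0.74,0.86
age_30_39,short_term,-0.2741,0.0370,0.76,0.71,0.82
age_40_49,short_term,-0.2415,0.0372,0.79,0.73,0.84
age_50_59,short_term,-0.0919,0.0376,0.91,0.85,0.98
age_60_69,short_term,0.0821,0.0370,1.09,1.01,1.17
age_70_79,short_term,0.3315,0.0368,1.39,1.30,1.50
age_80_plus,short_term,0.6837,0.0370,1.98,1.84,2.13
sex_female,short_term,-0.0364,0.0018,0.96,0.96,0.97
race_black,short_term,-0.3395,0.0023,0.71,0.71,0.71
race_asian,short_term,-0.3992,0.0058,0.67,0.66,0.68
race_american_indian,short_term,-0.2344,0.0084,0.79,0.78,0.80
race_nhpi,short_term,-0.3785,0.0099,0.69,0.67,0.70
race_other,short_term,0.0812,0.0169,1.08,1.05,1.12
hispanic_yes,short_term,-0.3438,0.0033,0.71,0.70,0.71
disease_hypertension,short_term,-0.0221,0.0021,0.98,0.97,0.98
disease_gn_cystic,short_term,-0.2047,0.0040,0.81,0.81,0.82
disease_other,short_term,0.1179,0.0034,1.12,1.12,1.13
liu_index,short_term,0.0565,0.0014,1.06,1.06,1.06
inability_ambulate_yes,short_term,0.2271,0.0056,1.25,1.24,1.27
inability_transfer_yes,short_term,0.2258,0.0077,1.25,1.24,1.27
needs_assistance_yes,short_term,0.0314,0.0038,1.03,1.02,1.04
inst_nursing_home,short_term,0.2576,0.0050,1.29,1.28,1.31
inst_assisted_living,short_term,0.0882,0.0117,1.09,1.07,1.12
inst_other,short_term,0.0631,0.0159,1.06,1.03,1.10
alcohol_yes,short_term,0.2101,0.0098,1.23,1.21,1.26
tobacco_yes,short_term,0.0954,0.0042,1.10,1.09,1.11
drug_yes,short_term,0.1756,0.0094,1.19,1.17,1.21
amputation_yes,short_term,0.0337,0.0055,1.03,1.02,1.04
toxic_nephropathy_yes,short_term,-0.0589,0.0205,0.94,0.91,0.98
peritoneal,short_term,-0.0698,0.0031,0.93,0.93,0.94
transplant,short_term,-1.5837,0.0060,0.20,0.20,0.21
employment_employed,short_term,-0.2440,0.0046,0.78,0.78,0.79
employment_retired_age,short_term,-0.0028,0.0033,1.00,0.99,1.00
employment_retired_disabled,short_term,0.0407,0.0028,1.04,1.04,1.05
employment_other,short_term,-0.1441,0.0077,0.87,0.85,0.88
ins_medicaid_only,short_term,0.0063,0.0051,1.01,1.00,1.02
ins_medicare_only,short_term,0.0310,0.0041,1.03,1.02,1.04
ins_dva_plus,short_term,-0.0355,0.0068,0.96,0.95,0.98
ins_medicare_employer,short_term,0.0485,0.0047,1.05,1.04,1.06
ins_medicare_medicaid,short_term,0.1143,0.0044,1.12,1.11,1.13
ins_multiple_otherwise,short_term,0.0665,0.0043,1.07,1.06,1.08
ins_other,short_term,0.0245,0.0055,1.02,1.01,1.04
ins_none,short_term,-0.1368,0.0061,0.87,0.86,0.88
rural_large,short_term,-0.0092,0.0032,0.99,0.98,1.00
rural_small,short_term,-0.0208,0.0043,0.98,0.97,0.99
rural_isolated,short_term,0.0138,0.0050,1.01,1.00,1.02
region_south,short_term,0.0843,0.0028,1.09,1.08,1.09
region_midwest,short_term,0.0429,0.0030,1.04,1.04,1.05
region_northeast,short_term,0.0301,0.0035,1.03,1.02,1.04
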