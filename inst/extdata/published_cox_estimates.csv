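term,coef,se,ratio,ci_lo,ci_hi
age_18_29,0.2441,0.0222,1.28,1.22,1.33
age_30_39,0.5811,0.0210,1.79,1.72,1.86
age_40_49,0.8579,0.0207,2.36,2.26,2.46
age_50_59,1.1250,0.0206,3.08,2.96,3.21
age_60_69,1.3628,0.0206,3.91,3.75,4.07
age_70_79,1.6626,0.0207,5.27,5.06,5.50
age_80_plus,2.0382,0.0207,7.68,7.37,8.00
sex_female,-0.0280,0.0017,0.97,0.97,0.98
race_black,-0.3000,0.0020,0.74,0.74,0.74
race_asian,-0.4649,0.0049,0.63,0.62,0.63
race_american_indian,-0.1673,0.0078,0.85,0.83,0.86
race_nhpi,-0.3758,0.0091,0.69,0.68,0.70
race_other,-0.0490,0.0135,0.95,0.92,0.98
hispanic_yes,-0.3773,0.0028,0.69,0.68,0.69
disease_hypertension,-0.0911,0.0020,0.91,0.91,0.92
disease_gn_cystic,-0.3425,0.0033,0.71,0.71,0.71
disease_other,-0.0287,0.0025,0.97,0.97,0.98
liu_index,0.0623,0.0003,1.06,1.06,1.06
inability_ambulate_yes,0.2178,0.0041,1.24,1.23,1.25
inability_transfer_yes,0.1884,0.0053,1.21,1.19,1.22
needs_assistance_yes,0.0207,0.0031,1.02,1.01,1.03
inst_nursing_home,0.2082,0.0038,1.23,1.22,1.24
inst_assisted_living,0.0779,0.0102,1.08,1.06,1.10
inst_other,0.0268,0.0115,1.03,1.00,1.05
alcohol_yes,0.1498,0.0066,1.16,1.14,1.18
tobacco_yes,0.1491,0.0034,1.16,1.15,1.17
drug_yes,0.1533,0.0077,1.17,1.15,1.19
amputation_yes,0.0478,0.0049,1.05,1.04,1.06
toxic_nephropathy_yes,-0.1473,0.0145,0.86,0.84,0.89
peritoneal,-0.3107,0.0046,0.73,0.73,0.74
peritoneal_time,0.0607,0.0011,1.06,1.06,1.06
transplant,-1.8829,0.0113,0.15,0.15,0.16
transplant_time,0.0704,0.0012,1.07,1.07,1.08
employment_employed,-0.3061,0.0039,0.74,0.73,0.74
employment_retired_age,0.0126,0.0025,1.01,1.01,1.02
employment_retired_disabled,0.0684,0.0025,1.07,1.06,1.08
employment_other,-0.1940,0.0059,0.82,0.81,0.83
ins_medicaid_only,0.0609,0.0040,1.06,1.05,1.07
ins_medicare_only,0.1254,0.0036,1.13,1.13,1.14
ins_dva_plus,0.0418,0.0065,1.04,1.03,1.06
ins_medicare_employer,0.1316,0.0042,1.14,1.13,1.15
ins_medicare_medicaid,0.2195,0.0038,1.25,1.24,1.25
ins_multiple_otherwise,0.1693,0.0038,1.18,1.18,1.19
ins_other,0.0553,0.0045,1.06,1.05,1.07
ins_none,-0.1003,0.0047,0.91,0.90,0.91
rural_large,0.0081,0.0028,1.01,1.00,1.01
rural_small,-0.0003,0.0038,1.00,0.99,1.01
rural_isolated,0.0269,0.0049,1.03,1.02,1.04
region_south,0.0962,0.0024,1.10,1.10,1.11
region_midwest,0.0392,0.0026,1.04,1.03,1.05
region_northeast,0.0226,0.0027,1.02,1.02,1.03
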