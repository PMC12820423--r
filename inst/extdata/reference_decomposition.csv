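rank_variable,feature,importance,feature_ci,feature_ci_se,printed_value,printed_digits,consistent
wealth_quintile,wealth_quintile,0.055,0.3029,0.0021,0.017,3,TRUE
wealth_quintile,education_level,0.060,0.2583,0.003,0.016,3,FALSE
wealth_quintile,ethnicity,0.021,0.000,0.000,0.000,3,TRUE
wealth_quintile,age_group,0.034,-0.009,0.001,0.000,3,TRUE
wealth_quintile,state,0.275,0.003,0.002,0.001,3,TRUE
wealth_quintile,residence,0.138,-0.067,0.001,-0.001,3,FALSE
wealth_quintile,met_chw,0.026,-0.042,0.004,-0.001,3,TRUE
wealth_quintile,chw_type,0.021,-0.025,0.004,-0.001,3,TRUE
wealth_quintile,female_provider_unavailable,0.004,-0.102,0.0029,0.000,3,TRUE
wealth_quintile,autonomy_index,0.089,-0.111,0.005,-0.010,3,TRUE
wealth_quintile,hesitancy,0.018,-0.136,0.0036,-0.002,3,TRUE
wealth_quintile,safe_water,0.021,0.143,0.0123,0.003,3,TRUE
wealth_quintile,sanitation,0.010,0.221,0.003,0.0022,4,TRUE
wealth_quintile,distance_problem,0.031,-0.147,0.003,-0.005,3,TRUE
wealth_quintile,transport_problem,0.010,-0.159,0.003,-0.002,3,TRUE
wealth_quintile,insurance,0.015,-0.042,0.005,-0.001,3,TRUE
wealth_quintile,money_for_treatment,0.028,-0.172,0.0035,-0.005,3,TRUE
wealth_quintile,occupation,0.018,-0.017,0.0022,0.000,3,TRUE
wealth_quintile,services_discussed,0.088,0.034,0.0099,0.003,3,TRUE
wealth_quintile,pqc_index,0.038,-0.088,0.0024,-0.003,3,TRUE
education_level,wealth_quintile,0.055,0.185,0.0021,0.010,3,TRUE
education_level,education_level,0.060,0.429,0.003,0.026,3,TRUE
education_level,ethnicity,0.021,0.000,0.000,0.000,3,TRUE
education_level,age_group,0.034,-0.015,0.0006,-0.001,3,TRUE
education_level,state,0.275,0.041,0.0022,0.011,3,TRUE
education_level,residence,0.138,-0.042,0.001,-0.006,3,TRUE
education_level,met_chw,0.026,-0.011,0.004,-0.0003,4,TRUE
education_level,chw_type,0.021,0.003,0.004,0.000,3,TRUE
education_level,female_provider_unavailable,0.004,-0.088,0.003,0.000,3,TRUE
education_level,autonomy_index,0.089,-0.118,0.005,-0.012,3,FALSE
education_level,hesitancy,0.018,-0.112,0.004,-0.002,3,TRUE
education_level,safe_water,0.021,0.096,0.0123,0.002,3,TRUE
education_level,sanitation,0.010,0.130,0.003,0.001,3,TRUE
education_level,distance_problem,0.031,-0.112,0.003,-0.003,3,TRUE
education_level,transport_problem,0.010,-0.122,0.003,-0.001,3,TRUE
education_level,insurance,0.015,0.006,0.006,0.000,3,TRUE
education_level,money_for_treatment,0.028,-0.134,0.004,-0.004,3,TRUE
education_level,occupation,0.018,-0.009,0.0022,0.000,3,TRUE
education_level,services_discussed,0.088,0.057,0.0099,0.005,3,TRUE
education_level,pqc_index,0.038,-0.068,0.0024,-0.0026,4,TRUE
ethnicity,wealth_quintile,0.055,-0.026,0.0021,-0.001,3,TRUE
ethnicity,education_level,0.060,-0.027,0.003,-0.002,3,TRUE
ethnicity,ethnicity,0.021,0.000,0.000,0.000,3,TRUE
ethnicity,age_group,0.034,0.007,0.001,0.000,3,TRUE
ethnicity,state,0.275,-0.100,0.002,-0.028,3,TRUE
ethnicity,residence,0.138,0.011,0.001,0.002,3,TRUE
ethnicity,met_chw,0.026,-0.037,0.0042,-0.001,3,TRUE
ethnicity,chw_type,0.021,-0.035,0.0044,-0.001,3,TRUE
ethnicity,female_provider_unavailable,0.004,0.003,0.003,0.000,3,TRUE
ethnicity,autonomy_index,0.089,-0.012,0.005,-0.001,3,TRUE
ethnicity,hesitancy,0.018,0.007,0.004,0.000,3,TRUE
ethnicity,safe_water,0.021,-0.080,0.0123,-0.002,3,TRUE
ethnicity,sanitation,0.010,0.021,0.003,0.000,3,TRUE
ethnicity,distance_problem,0.031,0.021,0.003,0.001,3,TRUE
ethnicity,transport_problem,0.010,0.020,0.003,0.000,3,TRUE
ethnicity,insurance,0.015,0.001,0.006,0.000,3,TRUE
ethnicity,money_for_treatment,0.028,0.017,0.004,0.001,3,FALSE
ethnicity,occupation,0.018,0.006,0.002,0.000,3,TRUE
ethnicity,services_discussed,0.088,-0.040,0.010,-0.004,3,TRUE
ethnicity,pqc_index,0.038,0.011,0.002,0.000,3,TRUE
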