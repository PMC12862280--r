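dimension,indicator,variant,cluster_mean,printed_delta,state_mean,arithmetic_consistent
age,median_age_years,ice_income,41.5,0.8,40.7,TRUE
age,median_age_years,ice_race,35.1,-5.6,40.7,TRUE
age,median_age_years,ice_race_income,44.6,3.9,40.7,TRUE
age,under_5_pct,ice_income,3.6,-1.9,5.5,TRUE
age,under_5_pct,ice_race,2.6,-2.9,5.5,TRUE
age,under_5_pct,ice_race_income,3.1,-2.4,5.5,TRUE
age,over_65_pct,ice_income,35.6,18.4,17.2,TRUE
age,over_65_pct,ice_race,22.4,5.2,17.2,TRUE
age,over_65_pct,ice_race_income,31.6,14.4,17.2,TRUE
education,no_high_school_pct,ice_income,10.2,-1.3,11.5,TRUE
education,no_high_school_pct,ice_race,8.3,-3.2,11.5,TRUE
education,no_high_school_pct,ice_race_income,10.7,-0.8,11.5,TRUE
employment,unemployment_pct,ice_income,4.9,-0.6,5.5,TRUE
employment,unemployment_pct,ice_race,4.2,-1.3,5.5,TRUE
employment,unemployment_pct,ice_race_income,4.6,-0.9,5.5,TRUE
health,no_health_insurance_pct,ice_income,10.8,-0.1,10.9,TRUE
health,no_health_insurance_pct,ice_race,7.8,-3.1,10.9,TRUE
health,no_health_insurance_pct,ice_race_income,10.9,0.0,10.9,TRUE
housing,renters_pct,ice_income,26.2,-7.7,33.9,TRUE
housing,renters_pct,ice_race,19.6,-14.3,33.9,TRUE
housing,renters_pct,ice_race_income,28.2,-5.7,33.9,TRUE
housing,mobile_homes_pct,ice_income,17.2,4.5,12.7,TRUE
housing,mobile_homes_pct,ice_race,12.1,-0.6,12.7,TRUE
housing,mobile_homes_pct,ice_race_income,17.0,4.3,12.7,TRUE
housing,median_housing_value_usd,ice_income,204741,-9391,214132,TRUE
housing,median_housing_value_usd,ice_race,100263,-113869,214132,TRUE
housing,median_housing_value_usd,ice_race_income,162546,-51586,214132,TRUE
housing,rent_burden_over_30pct,ice_income,41.5,1.4,40.0,FALSE
housing,rent_burden_over_30pct,ice_race,22.6,-17.4,40.0,TRUE
housing,rent_burden_over_30pct,ice_race_income,39.8,-0.2,40.0,TRUE
income,median_household_income_usd,ice_income,46708,-17752,64460,TRUE
income,median_household_income_usd,ice_race,32769,-31691,64460,TRUE
income,median_household_income_usd,ice_race_income,39920,-24540,64460,TRUE
dependence,social_security_pct,ice_income,39.9,6.5,33.4,TRUE
dependence,social_security_pct,ice_race,27.6,-5.8,33.4,TRUE
dependence,social_security_pct,ice_race_income,36.2,2.8,33.4,TRUE
race_ethnicity,white_pct,ice_income,73.4,6.7,66.7,TRUE
race_ethnicity,white_pct,ice_race,30.3,-36.4,66.7,TRUE
race_ethnicity,white_pct,ice_race_income,61.0,-5.7,66.7,TRUE
race_ethnicity,black_pct,ice_income,6.9,-14.3,21.2,TRUE
race_ethnicity,black_pct,ice_race,20.9,-0.3,21.2,TRUE
race_ethnicity,black_pct,ice_race_income,11.4,-9.8,21.2,TRUE
race_ethnicity,asian_pct,ice_income,0.5,-2.2,2.7,TRUE
race_ethnicity,asian_pct,ice_race,0.3,-2.3,2.7,FALSE
race_ethnicity,asian_pct,ice_race_income,0.5,-2.2,2.7,TRUE
race_ethnicity,hispanic_pct,ice_income,5.3,-4.0,9.3,TRUE
race_ethnicity,hispanic_pct,ice_race,4.5,-4.8,9.3,TRUE
race_ethnicity,hispanic_pct,ice_race_income,5.6,-3.7,9.3,TRUE
mobility,no_vehicle_pct,ice_income,6.4,0.5,5.9,TRUE
mobility,no_vehicle_pct,ice_race,5.8,-0.1,5.9,TRUE
mobility,no_vehicle_pct,ice_race_income,7.7,1.8,5.9,TRUE
internet,no_internet_pct,ice_income,13.0,0.3,12.7,TRUE
internet,no_internet_pct,ice_race,9.9,-2.8,12.7,TRUE
internet,no_internet_pct,ice_race_income,13.2,0.5,12.7,TRUE
internet,no_computer_pct,ice_income,9.6,1.1,8.5,TRUE
internet,no_computer_pct,ice_race,7.8,-0.7,8.5,TRUE
internet,no_computer_pct,ice_race_income,9.5,1.0,8.5,TRUE
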