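quantity,value
ed_visits_total,8611
firearm_injuries_total,342
geocoded_cases,269
api_coordinates_confirmed,208
coordinates_corrected_manually,61
cases_in_study_area,248
study_days,406
days_with_records,273
communal_sections,16
neighborhood_estimates,106
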