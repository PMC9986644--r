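parameter,unit,child,adult
body_weight,kg,15,70
exposure_frequency,days/year,350,350
exposure_duration,years,6,30
ingestion_rate,mg/day,200,100
inhalation_rate,m3/day,10,20
skin_area,cm2,2100,5800
adherence_factor,mg/cm2,0.2,0.07
dermal_absorption,-,0.1,0.1
dermal_exposure_ratio,-,0.61,0.61
particulate_emission_factor,m3/kg,1.3e9,1.3e9
conversion_factor,kg/mg,1e-6,1e-6
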