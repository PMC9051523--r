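quantity,value,unit,description
externality_cost_per_kg,16.1,US$/kg N,monetized groundwater-contamination damage per kg N leached
state_maize_area_ha,4400000,ha,yearly maize production area of Illinois
policy_cost_total_usd_yr,147000000,US$/yr,published state-scale policy cost at the 20% leaching-reduction target
load_reduction_kg_yr,32600000,kg N/yr,published state-scale N load reduction at the 20% target
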