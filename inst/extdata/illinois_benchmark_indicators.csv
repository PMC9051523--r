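scope,region,policy,sublevel,yield_t_ha,leach_kg_ha,n_fert_kg_ha,profits_usd_ha,gov_collections_usd_ha,policy_cost_usd_ha,abatement_cost_usd_kg_ha
state,state,base,NA,12.6,38.8,176,1849,NA,NA,NA
state,state,price_ratio,12.9,12.2,31.4,143,1637,179,33,4.5
state,state,leaching_fee,13.2,12.2,31.4,144,1682,138,30,4.1
state,state,balance_fee,1.8,12.2,31.2,142,1763,52,35,4.6
state,state,voluntary,18.5,12.2,31.4,143,1812,0,37,5
region,south,base,NA,12.1,35.9,193,1754,NA,NA,NA
region,south,price_ratio,12.9,11.7,27.9,159,1522,199,34,4.3
region,south,leaching_fee,13.2,11.7,27.9,160,1598,124,32,4
region,south,balance_fee,1.8,11.7,27.6,158,1658,60,36,4.4
region,south,voluntary,18.5,11.6,27.2,156,1712,0,42,4.8
region,central,base,NA,12.5,37.0,176,1844,NA,NA,NA
region,central,price_ratio,12.9,12.2,30.5,144,1627,180,37,5.7
region,central,leaching_fee,13.2,12.2,30.7,146,1680,131,32,5
region,central,balance_fee,1.8,12.1,30.3,143,1755,49,39,5.8
region,central,voluntary,18.5,12.1,30.5,143,1801,0,43,6.6
region,north,base,NA,13.2,43.8,158,1954,NA,NA,NA
region,north,price_ratio,12.9,12.8,35.9,125,1769,156,29,3.7
region,north,leaching_fee,13.2,12.8,35.8,126,1770,158,26,3.3
region,north,balance_fee,1.8,12.8,36.0,126,1879,47,28,3.6
region,north,voluntary,18.5,12.8,36.7,128,1928,0,26,3.7
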