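dcm_id,name,sample_size,target_population,total_annual_cost,apportion_percent
census,National housing and population census,33000000,33000000,8500000,25
NHS,National Household Survey,23000,33000000,840000,5
DHS,Demographic and Health Survey,15000,33000000,870000,10
HMS,Health management system,17000000,33000000,2200000,20
IDS,Integrated disease surveillance,3000000,6000000,4500000,15
X-DSS,Demographic surveillance system Region X,66000,510000,200000,40
Y-DSS,Demographic surveillance system Region Y,83000,180000,220000,40
MM,Adult morbidity and mortality project,500000,2600000,100000,60
A-DSS,Demographic surveillance system for AIDS,23000,23000,15000,30
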