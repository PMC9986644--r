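scheme,lower,upper,label
cf_hakanson,-Inf,1,Low
cf_hakanson,1,3,Moderate
cf_hakanson,3,6,Considerable
cf_hakanson,6,Inf,Very high
cd_hakanson,-Inf,8,Low
cd_hakanson,8,16,Moderate
cd_hakanson,16,32,Considerable
cd_hakanson,32,Inf,Very high
cd_inferred,-Inf,6,Low
cd_inferred,6,10,Moderate
cd_inferred,10,20,Considerable
cd_inferred,20,Inf,High
igeo_muller,-Inf,0,Unpolluted
igeo_muller,0,1,Unpolluted to moderately polluted
igeo_muller,1,2,Moderately polluted
igeo_muller,2,3,Moderately to heavily polluted
igeo_muller,3,4,Heavily polluted
igeo_muller,4,5,Heavily to extremely polluted
igeo_muller,5,Inf,Extremely polluted
pli_tomlinson,-Inf,1,Baseline
pli_tomlinson,1,Inf,Deteriorating
ef_standard,-Inf,2,Minimal enrichment
ef_standard,2,5,Moderate enrichment
ef_standard,5,20,Significant enrichment
ef_standard,20,40,Very high enrichment
ef_standard,40,Inf,Extremely high enrichment
er_hakanson,-Inf,40,Low
er_hakanson,40,80,Moderate
er_hakanson,80,160,Considerable
er_hakanson,160,320,High
er_hakanson,320,Inf,Very high
peri_hakanson,-Inf,150,Low
peri_hakanson,150,300,Moderate
peri_hakanson,300,600,Considerable
peri_hakanson,600,Inf,Very high
peri_inferred,-Inf,150,Moderate
peri_inferred,150,200,Considerable
peri_inferred,200,Inf,Very high
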