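risk_id,canonical_name,level,parent_id,group
all_risk,All risk factors,0,,all_risks
behavioral,Behavioral risks,1,all_risk,behavioral
dietary_risks,Dietary risks,2,behavioral,behavioral
low_physical_activity,Low physical activity,2,behavioral,behavioral
diet_red_meat,Diet high in red meat,3,dietary_risks,behavioral
diet_processed_meat,Diet high in processed meat,3,dietary_risks,behavioral
diet_ssb,Diet high in sugar-sweetened beverages,3,dietary_risks,behavioral
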