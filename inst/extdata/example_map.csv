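raw_name,iteration,risk_id
Diet high in red meat,,diet_red_meat
Diet high in red meat consumption,2015,diet_red_meat
Diet high in processed meat,,diet_processed_meat
Diet high in sugar-sweetened beverages,,diet_ssb
Diet high in sugar sweetened beverages,2015,diet_ssb
Low physical activity,,low_physical_activity
Physical inactivity and low physical activity,2015,low_physical_activity
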