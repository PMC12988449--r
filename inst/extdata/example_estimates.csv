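risk,metric,iteration,year,value,ui_lower,ui_upper
Diet high in red meat consumption,deaths,2015,2015,57000,,
Diet high in red meat,deaths,2017,2015,50000,,
Diet high in red meat,deaths,2017,2017,25000,,
Diet high in red meat,deaths,2019,2015,872000,610000,1150000
Diet high in red meat,deaths,2019,2017,881000,620000,1160000
Diet high in red meat,deaths,2019,2019,896000,640000,1180000
Diet high in red meat,deaths,2021,2015,842000,420000,1300000
Diet high in red meat,deaths,2021,2017,850000,430000,1320000
Diet high in red meat,deaths,2021,2019,861000,440000,1340000
Diet high in red meat,deaths,2021,2021,93000,46000,180000
Diet high in processed meat,deaths,2015,2015,305000,,
Diet high in processed meat,deaths,2017,2015,300000,,
Diet high in processed meat,deaths,2017,2017,306000,,
Diet high in processed meat,deaths,2019,2015,130000,90000,180000
Diet high in processed meat,deaths,2019,2017,133000,92000,184000
Diet high in processed meat,deaths,2019,2019,137000,95000,190000
Diet high in processed meat,deaths,2021,2015,820000,410000,1250000
Diet high in processed meat,deaths,2021,2017,828000,415000,1260000
Diet high in processed meat,deaths,2021,2019,835000,420000,1275000
Diet high in processed meat,deaths,2021,2021,841000,425000,1290000
Diet high in sugar sweetened beverages,deaths,2015,2015,125000,,
Diet high in sugar-sweetened beverages,deaths,2017,2015,122000,,
Diet high in sugar-sweetened beverages,deaths,2017,2017,130000,,
Diet high in sugar-sweetened beverages,deaths,2019,2015,23000,15000,33000
Diet high in sugar-sweetened beverages,deaths,2019,2017,24500,16000,35000
Diet high in sugar-sweetened beverages,deaths,2019,2019,26000,17000,37000
Diet high in sugar-sweetened beverages,deaths,2021,2015,285000,140000,460000
Diet high in sugar-sweetened beverages,deaths,2021,2017,292000,145000,470000
Diet high in sugar-sweetened beverages,deaths,2021,2019,297000,148000,478000
Diet high in sugar-sweetened beverages,deaths,2021,2021,300000,150000,485000
Physical inactivity and low physical activity,deaths,2015,2015,1650000,,
Low physical activity,deaths,2017,2015,1580000,,
Low physical activity,deaths,2017,2017,1320000,,
Low physical activity,deaths,2019,2015,900000,700000,1150000
Low physical activity,deaths,2019,2017,880000,690000,1120000
Low physical activity,deaths,2019,2019,860000,680000,1100000
Low physical activity,deaths,2021,2015,700000,480000,980000
Low physical activity,deaths,2021,2017,690000,470000,960000
Low physical activity,deaths,2021,2019,680000,460000,950000
Low physical activity,deaths,2021,2021,658000,440000,930000
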