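variant_id	replicate	amount_c15	amount_c17_1	amount_c17_0
marine1	1	0.3427455114587267	0.09758527404166362	0.03527623089247208
marine1	2	0.2692868378722669	0.0577662052397846	0.018271986212461143
marine1	3	0.3180834459050548	0.078391368586278945	0.0172967488285956
marine2	1	0.01755573235758737	0.002957307066692594	0.0017246094887012698
marine2	2	0.014471459613356025	0.003952237646826742	0.001178791644355834
marine2	3	0.019586788138461	0.003556705816970575	0.0018022807609300948
fresh1	1	0.015997541958630977	0.06422182190351196	0.007378905327027858
fresh1	2	0.017678799716705523	0.06310880403544371	0.0028776614567616646
fresh1	3	0.011312717951358478	0.06527205415487264	0.010982857345888877
fresh2	1	0.06631305593311412	0.2746363948259493	0.044166273349139674
fresh2	2	0.07522132113268007	0.32605397531123664	0.037959847990752624
fresh2	3	0.08869505508287538	0.2808196856097555	0.02208364587763839
fresh3	1	0.7000495166794496	1.748181870273539	0.09133440519369422
fresh3	2	0.47926825097445996	1.8009339598421048	0.22050462620680492
fresh3	3	0.5009300877984108	1.6057241564110367	0.07742425302308661
fresh4	1	0.03262737879630639	0.15292627293579167	0.008575872271818379
fresh4	2	0.028908555404976364	0.12593445652736726	0.014781018365930496
fresh4	3	0.03485600413853811	0.12183860012293003	0.009124369421784783
fresh5	1	0.011907131140304488	0.0626891467668084	0.0020503856906914186
fresh5	2	0.013271938269480428	0.06955583238808406	0.011769644804739927
fresh5	3	0.019091187205435286	0.06087108163295342	0.008157457340152436
fresh6	1	0.01581590646134094	0.0894846190455037	0.007243197426074814
fresh6	2	0.01790589863358127	0.07914045275489288	0.009470110897449525
fresh6	3	0.015390966388915883	0.08008391917063956	0.0074337625058471715
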