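variant_id	replicate	soluble_volume	insoluble_volume	soluble_detected	insoluble_detected
marine1	1	0.44695986507942415	0.5631284394741912	TRUE	TRUE
marine1	2	0.4359780327281663	0.4950790733710902	TRUE	TRUE
marine1	3	0.39913696490538264	0.5919354555093131	TRUE	TRUE
marine2	1	0.10021720944481387	0.24745860732494696	TRUE	TRUE
marine2	2	0.11466970127368582	0.25688340269089077	TRUE	TRUE
marine2	3	0.09461741816425882	0.24572435616821045	TRUE	TRUE
fresh1	1	0.1384376620044074	0.4005235889066879	TRUE	TRUE
fresh1	2	0.1353811764490132	0.418887927779353	TRUE	TRUE
fresh1	3	0.12752472483640634	0.35905555729208527	TRUE	TRUE
fresh2	1	0.19618050673856913	0.281114758051982	TRUE	TRUE
fresh2	2	0.24505459425109663	0.19526844951643568	TRUE	TRUE
fresh2	3	0.22346453311608092	0.280227650549597	TRUE	TRUE
fresh3	1	1.1589266147374784	2.475370136985808	TRUE	TRUE
fresh3	2	1.138306431297994	2.2527766102911237	TRUE	TRUE
fresh3	3	1.281046878965394	2.0838306791553345	TRUE	TRUE
fresh4	1	0.16453557166908925	1.1010120614641865	TRUE	TRUE
fresh4	2	0.1993749185835391	1.0363384675165166	TRUE	TRUE
fresh4	3	0.206314349084028	0.918883956893015	TRUE	TRUE
fresh5	1	0.25697698295636445	0.5300307105249046	TRUE	TRUE
fresh5	2	0.3043303825114289	0.5706760197691062	TRUE	TRUE
fresh5	3	0.2883245924595542	0.641654733100209	TRUE	TRUE
fresh6	1	0.04379014383794262	0.6321744443427361	TRUE	TRUE
fresh6	2	0.043628370007671384	0.5573144214016197	TRUE	TRUE
fresh6	3	0.047126222149661445	0.4966872763307372	TRUE	TRUE
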