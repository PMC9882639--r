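item_id	lambdaG	lambdaS	specific
SEQ2 Q9/SEQ3 Q17	0.691	0.409	Visual
SP1 Q97/SP2 Q80/SP2 Q81	0.593	0.296	Visual
SEQ3 Q19	0.656	0.310	Visual
SEQ3 Q27	0.552	0.558	Visual
SEQ3 Q29	0.526	0.487	Visual
SEQ3 Q30	0.572	0.486	Visual
SP1 Q45/SP2 Q21/SP2 Q25	0.598	0.364	Tactile
SEQ2 Q36f/SEQ3 Q45	0.551	0.688	Tactile
SEQ3 Q37	0.436	0.413	Tactile
SEQ3 Q50	0.672	0.131	Tactile
SEQ2 Q25/SEQ3 Q62	0.441	0.796	OralTactile
SP1 Q64	0.433	0.856	OralTactile
SP1 Q65	0.421	0.772	OralTactile
SEQ3 Q71	0.525	0.706	OralTactile
SP1 Q24/SP1 Q25/SP2 Q27	0.611	0.483	Movement
SEQ2 Q27/SEQ3 Q76	0.624	0.358	Movement
SP1 Q84/SP2 Q60	0.599	0.160	Movement
SP1 Q26	0.683	0.651	Movement
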