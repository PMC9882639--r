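item_id	lambdaG	lambdaS	specific
SEQ2 Q3/SEQ3 Q8	0.446	0.725	Speech
SP1 Q6/SP2 Q6	0.344	0.726	Speech
SP1 Q7/SP2 Q7	0.416	0.848	Speech
SEQ2 Q19/SEQ3 Q53	0.413	0.690	PainTemp
SP1 Q42/SP2 Q23/SP2 Q24	0.441	0.870	PainTemp
SEQ3 Q56	0.447	0.478	PainTemp
SEQ2 Q10/SEQ3 Q22/SEQ3 Q23 [Visual]	0.541	0	NA
SP1 Q46/SP2 Q26 [Tactile]	0.470	0	NA
SEQ2 Q4/SEQ3 Q4 [Auditory]	0.554	0	NA
SEQ3 Q69 [Olfactory]	0.445	0	NA
SEQ3 Q74 [Gustatory]	0.448	0	NA
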