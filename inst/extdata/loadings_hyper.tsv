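item_id	lambdaG	lambdaS	specific
SP1 Q1/SP2 Q1	0.513	0.699	Auditory
SP1 Q2/SP2 Q2	0.469	0.683	Auditory
SEQ2 Q1/SEQ3 Q1	0.469	0.753	Auditory
SEQ3 Q9	0.611	0.475	Auditory
SEQ2 Q8/SEQ3 Q15	0.571	0.594	Visual
SP1 Q10/SP2 Q15	0.563	0.677	Visual
SP1 Q14/SP2 Q13	0.649	0.601	Visual
SP1 Q15	0.565	0.599	Visual
SP1 Q30/SP2 Q16/SEQ2 Q15/SEQ3 Q49	0.449	0.449	Tactile
SP1 Q36/SP2 Q18	0.608	0.261	Tactile
SEQ2 Q16/SEQ3 Q38	0.564	0.100	Tactile
SP1 Q33	0.650	0.324	Tactile
SEQ2 Q22/SEQ3 Q59	0.451	0.695	Gustatory
SP1 Q55/SP2 Q44	0.465	0.786	Gustatory
SP1 Q56/SP2 Q45	0.454	0.721	Gustatory
SEQ3 Q70	0.482	0.393	Gustatory
SEQ3 Q61	0.619	0.685	Olfactory
SEQ3 Q66	0.543	0.713	Olfactory
SEQ3 Q73	0.547	0.413	Olfactory
SP1 Q18	0.482	0.701	Movement
SP1 Q19	0.462	0.680	Movement
SP1 Q20	0.408	0.637	Movement
SEQ3 Q83	0.464	0.621	Movement
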