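reaction	stoichiometry	transition
V_1	A -> B	#AB -> #BA
V_2	B -> C	#AB -> #AB
V_3	B + C -> D	#AB + #CD -> #ABCD
V_4	C -> E	#AB -> #BA
V_5	C + E -> F	#AB + #CD -> #ABCD
V_6	B -> B_OUT	#AB -> #AB
V_7	D -> D_OUT	#ABCD -> #ABCD
V_8	F -> F_OUT	#ABCD -> #ABCD
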