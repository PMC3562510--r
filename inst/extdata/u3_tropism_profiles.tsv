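group	probe	size_bp	repeat_1	unique_2	repeat_4	repeat_5	repeat_6	tata	insertion_190	tropism
I	B_3H-T_TH-1	603	+/+	+	+	+	+/+	+	+	P-II
II	B_3H-T_IN-3	556	+/+	.	+	+	+/+	+	+	P-I
III	B_3H-T_TH-7	440	+/+	+	+	+/+	+/+	+	.	X-II
IV	NB_24H-T_SC-3	433	+/+	.	+/+	+/+	+	+	.	X-II
V	B_3H-T_TH-6	392	+/+	+	+	+/+	+/+	+	.	X-I
VI	B_3H-B_ME-9	361	+/+	.	.	+/+	+/+	+	.	none
VII	B_3H-T_TH-11	346	+/+	+	+/+	.	+/+	+	.	X-II
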