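chromosome	arm	extension_span	extension_start_site	external_addition_site	external_repeat_span
Otip_I	L	16822	27184	10363	10362
Otip_I	R	24306	8885185	8860879	31405
Otip_II	L	10122	25180	15059	15058
Otip_II	R	10413	9010174	8999761	19801
Otip_III	L	4060	16298	12239	12238
Otip_III	R	25188	9621518	9596330	13932
Otip_IV	L	34114	39782	5669	5668
Otip_IV	R	4711	11184555	11179844	463
Otip_V	L	23599	30663	7065	7064
Otip_V	R	29106	10812563	10783457	4916
Otip_X	L	32697	51845	19149	19148
Otip_X	R	133498	11309184	11175686	14155
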