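statistic	population	era	value
theta	sumatra	modern	1.42
theta	borneo	modern	1.48
theta	malay_peninsula	modern	0.83
froh_2mb	sumatra	modern	0.086
froh_2mb	borneo	modern	0.045
froh_2mb	malay_peninsula	modern	0.30
froh_100kb	malay_peninsula	historical	0.44
froh_100kb	malay_peninsula	modern	0.65
froh_2mb	malay_peninsula	historical	0.078
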