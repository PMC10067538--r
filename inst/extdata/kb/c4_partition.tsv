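option	task_identify	task_compare	task_overview	single_genomic_axis	track_economy	cross_chromosome_context
contiguous	1	1	1	1	1	1
segregated	-1	-1	1	-1	-1	-1
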