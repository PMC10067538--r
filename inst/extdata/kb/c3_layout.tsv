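option	pos_length	color_only	task_identify	task_compare	task_overview	single_track	multi_track	quant_pos_length	focus_task	connection_sparse	connection_dense
linear	1	1	1	1	1	1	1	1	1	-1	-1
circular	1	1	1	1	1	1	1	-1	-1	1	1
space_filling	-1	1	-1	-1	1	1	-1	-1	-1	-1	-1
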