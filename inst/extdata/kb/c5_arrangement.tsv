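option	connection_none	connection_sparse	connection_dense	layout_linear	layout_circular	task_compare
single	1	-1	-1	1	1	-1
parallel	1	1	-1	1	-1	1
adjacent	-1	1	1	-1	1	-1
orthogonal	-1	-1	1	1	-1	-1
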