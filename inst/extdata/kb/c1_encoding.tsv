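option	point	segment	contiguous	sparse	quantitative	categorical	text	task_identify	task_compare	task_overview
rect_bar	1	-1	1	-1	1	-1	-1	1	1	1
line_position	1	-1	1	-1	1	-1	-1	1	1	1
point_position	1	-1	-1	1	1	-1	-1	1	1	1
rect_interval_saturation	1	1	1	1	1	-1	-1	-1	-1	1
rect_interval_hue	-1	1	-1	1	-1	1	-1	1	1	1
point_hue	1	-1	-1	1	-1	1	-1	1	1	1
text_position	1	1	-1	1	-1	-1	1	1	1	1
line_connection	1	1	-1	1	1	1	-1	-1	-1	-1
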