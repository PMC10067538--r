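option	multi_view	multi_track_view	task_identify	task_compare	task_overview
focus_context	-1	-1	1	1	-1
coordinated	-1	1	-1	-1	1
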