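option	same_file_multitrack	position_color_pair	multi_file
stacked	1	-1	1
overlayed	1	1	-1
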