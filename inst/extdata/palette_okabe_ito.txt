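# Colorblind-safe categorical palette (Okabe-Ito ordering), 8 colors.
# One hex color per line; assign_palette() takes prefixes of this list.
#E69F00
#56B4E9
#009E73
#F0E442
#0072B2
#D55E00
#CC79A7
#999999
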