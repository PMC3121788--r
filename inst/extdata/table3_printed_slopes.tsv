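label	t_start	t_end	slope
P0	0	5	-8.8
P0	5	15	-3.1
P0	15	30	-2.2
P0	30	60	-3.4
P7	0	5	-10.2
P7	5	15	-2.5
P7	15	30	-0.3
P7	30	60	-0.1
P80	0	5	-6.7
P80	5	15	-2.9
P80	15	30	-0.8
P80	30	60	-0.3
P540	0	5	-4.7
P540	5	15	-2.0
P540	15	30	-0.7
P540	30	60	-0.7
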