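label	time_min	pct_attached	sd	n
P0	0	100.0	NA	4
P0	5	55.9	NA	4
P0	15	24.5	NA	4
P0	30	17.6	NA	4
P0	60	8.8	NA	4
P7	0	100.0	NA	5
P7	5	49.2	NA	5
P7	15	24.3	NA	5
P7	30	20.5	NA	5
P7	60	17.4	NA	5
P80	0	100.0	NA	5
P80	5	66.4	NA	5
P80	15	37.7	NA	5
P80	30	25.0	NA	5
P80	60	17.4	NA	5
P540	0	100.0	NA	4
P540	5	76.5	NA	4
P540	15	57.0	NA	4
P540	30	46.1	NA	4
P540	60	26.4	NA	4
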