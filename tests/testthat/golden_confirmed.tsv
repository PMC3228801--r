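# package: comphot
# version: 0.1.0
# config: d0ba1f5c3d9b6174901fe83a05182f61
# seed: 7
id	winner	chrom	arm	strand	start	end	length	n_in_HIV	n_out_HIV	n_in_MLV	n_out_MLV	or	ci_lo	ci_hi	p_raw	p_adj	significant
mlv_1	MLV	sim1	q	+	676283	729238	52955	53	1147	329	871	8.17457704221996	6.03666897420572	11.06963295564538	5.72142075719747e-58	1.14428415143949e-57	TRUE
hiv_1	HIV	sim1	q	+	270571	337546	66975	319	881	56	1144	7.39695151613426	5.49488326829153	9.95742567413138	3.12581217699855e-53	3.12581217699855e-53	TRUE
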