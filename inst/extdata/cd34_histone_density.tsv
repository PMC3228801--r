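track	mean_hiv	sd_hiv	mean_mlv	sd_mlv	p_raw	adj_p
H3K27me3	0.002805	0.001179	0.003140	0.001585	0.069324	0.347210
H2AZ	0.003625	0.001441	0.004494	0.001444	2e-06	0.000018
H3K27me1	0.003399	0.000889	0.003774	0.001235	0.008568	0.050412
H3K36me3	0.006188	0.005843	0.005998	0.003063	0.766001	1
H3K4me1	0.002469	0.001630	0.003486	0.001823	6e-06	0.000096
H3K4me3	0.001617	0.001179	0.001078	0.000494	1e-06	0.000010
H3K9me1	0.006676	0.004553	0.008585	0.005302	0.00297	0.020986
H3K9me3	0.003696	0.003790	0.003555	0.001467	0.728885	1
H4K20me1	0.008214	0.005921	0.007407	0.004374	0.212219	0.846512
PolII	0.001876	0.000829	0.002016	0.001054	0.263484	0.846512
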