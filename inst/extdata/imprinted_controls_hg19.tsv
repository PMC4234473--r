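# Reference methylation percentages for control CpG islands (hg19, human
# anterior caudate nucleus, four adult subjects), for use as positive
# (imprinted, mid-level methylation) and negative (housekeeping promoter,
# near-zero methylation) alignment controls. Coordinates are 1-based
# inclusive CpG-island intervals. The sperm column is from an independent
# tissue and is annotation only: imprinting is tissue-specific and sperm
# values must never enter brain pass/fail logic.
gene	contig	start_hg19	end_hg19	polarity	B02	D07	E08	G12	sperm_pct	expected_mean_pct	expected_sd_pct
IGF2R	chr6	160426265	160427502	imprinted_mid	46.4	50.0	57.4	49.4	69.8	50.8	4.7
GRB10	chr7	50849753	50850871	imprinted_mid	24.8	28.5	27.2	24.5	45.2	26.3	1.9
PEG3	chr19	57351284	57351995	imprinted_mid	38.0	44.7	34.1	30.1	42.0	36.7	6.3
MEST	chr7	130130740	130133111	imprinted_mid	34.4	33.9	37.2	34.3	49.9	35.0	1.5
RB1	chr13	48892636	48893857	imprinted_mid	60.9	61.2	56.4	60.1	57.7	59.7	2.2
KCNQ1	chr11	2720411	2722087	imprinted_mid	39.2	36.9	36.4	36.9	50.4	37.4	1.3
GAPDH	chr12	6643262	6644607	unmethylated_low	1.4	0.7	1.8	1.3	NA	1.3	0.5
ACTB	chr7	5569063	5570594	unmethylated_low	0.8	0.4	1.7	1.0	NA	1.0	0.5
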