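# Normal/abnormal test-result counts by current diagnostic status, pooled over
# 6-36 months post-transplant, from a published three-year follow-up of 61
# double lung and heart-lung transplant recipients (58 analysed after
# excluding 3 patients ending follow-up in BOS 0-p with unresolved outcome).
# Dimensions: pct_basal = percent of the latest baseline, pct_pred = percent
# of predicted normal. Direction: abnormal strictly beyond the cutoff.
variable	dimension	direction	cutoff	nobos_normal	nobos_abnormal	bos_normal	bos_abnormal	bos0p_normal	bos0p_abnormal
FEV1	pct_basal	less	90	264	28	0	37	0	7
FVC	pct_basal	less	90	276	11	8	27	5	1
N2_slope	pct_basal	greater	299	240	12	12	13	4	3
FEV1	pct_pred	less	49	279	14	12	24	7	0
FVC	pct_pred	less	52	275	13	24	10	6	0
N2_slope	pct_pred	greater	478	234	18	1	24	0	7
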