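# Predictive-ability counts pooled over 6-24 months post-transplant from the
# same published transplant cohort: pre-diagnosis measurement occasions, the
# abnormal ones, and those abnormal occasions preceding a later BOS diagnosis.
criterion	total_results	total_abnormal	abnormal_preceding_bos
FEV1_lt90_basal	299	28	11
N2_gt478_pred	259	22	12
combined	259	12	9
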