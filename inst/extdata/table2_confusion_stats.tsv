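statistic	value
score_cutoff	-2.11
sensitivity_pct	68.62
specificity_pct	70
fpr_pct	30
ppv_pct	69.58
accuracy_pct	69.31
f1	0.69
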