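combination,n_predicted,tp,fp,fn,iou_pct,precision_pct,recall_pct,f1_pct
RGB,220,187,33,48,91.06,85,79.57,82.2
RGB-CHM,213,189,24,46,91.38,88.73,80.43,84.38
RGB-DSM,207,182,25,53,89.86,87.92,77.45,82.35
EXG,207,167,40,68,87.07,80.68,71.06,75.57
EXG-CHM,209,172,37,63,88.48,82.3,73.19,77.48
EXG-DSM,197,159,38,76,87.09,80.71,67.66,73.61
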