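# Published UAV vineyard trunk-detection evaluation: confusion counts and
# the rounded percentage metrics reported alongside them, for four point
# clouds (three single-flight reconstructions and their combination) and
# two training systems. Used to verify the precision/recall/F1 arithmetic.
dataset,system,tp,fp,fn,precision_pct,recall_pct,f1_pct
combined,SMPH,66,14,27,83,71,76
combined,VSP,54,5,70,92,44,59
tilted_20m,SMPH,83,9,10,90,89,90
tilted_20m,VSP,101,10,23,91,81,86
nadir_20m,SMPH,73,19,20,79,78,79
nadir_20m,VSP,111,11,13,91,90,91
nadir_15m,SMPH,67,11,26,86,72,78
nadir_15m,VSP,109,12,15,90,88,89
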