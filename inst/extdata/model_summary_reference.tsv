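ensemble	algorithm	accuracy_pct	roc_area
Boosting	BFTree	75.8	0.878
Boosting	J48	79.8	0.882
Boosting	LADTree	77.4	0.881
Boosting	SimpleCart	75.0	0.868
Boosting	FT	83.5	0.930
Boosting	LMT	81.8	0.936
Bagging	J48	75.4	0.868
Bagging	LADTree	75.0	0.876
Bagging	REPTree	75.0	0.870
Bagging	SimpleCart	76.2	0.855
Bagging	FT	82.7	0.937
Bagging	LMT	84.7	0.944
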