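fa	subgroup	antidepressant_history	antidepressant_current
0.263588	normal	No	No
0.332777	normal	Yes	Yes
0.353066	normal	Yes	Yes
0.362028	normal	Yes	No
0.390219	normal	No	No
0.39181	normal	Yes	No
0.410209	normal	Yes	Yes
0.417723	normal	No	No
0.434277	normal	No	No
0.43575	normal	No	No
0.448794	normal	Yes	Yes
0.455736	normal	Yes	No
0.544226	abnormal	Yes	No
0.546144	abnormal	No	No
0.54869	abnormal	Yes	No
0.602679	abnormal	Yes	Yes
0.603839	abnormal	No	No
0.612006	abnormal	Yes	No
0.646446	abnormal	Yes	Yes
0.658727	abnormal	Yes	Yes
0.67705	abnormal	No	No
0.745329	abnormal	Yes	No
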