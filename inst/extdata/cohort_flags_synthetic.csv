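patient,complete_metabolic_response,fdg_avid,has_post_scan,uptake_separable,glucose_baseline,glucose_post
1,FALSE,TRUE,TRUE,TRUE,5.2,5.6
2,FALSE,TRUE,TRUE,TRUE,6.1,5.9
3,TRUE,TRUE,TRUE,TRUE,5.4,5.1
4,FALSE,TRUE,TRUE,TRUE,4.9,5.3
5,FALSE,TRUE,TRUE,TRUE,5.8,6.0
6,FALSE,TRUE,FALSE,TRUE,5.5,
7,FALSE,TRUE,TRUE,TRUE,6.3,5.7
8,FALSE,TRUE,TRUE,TRUE,5.0,5.2
9,FALSE,TRUE,TRUE,TRUE,22.0,21.0
10,TRUE,TRUE,TRUE,TRUE,5.6,5.4
11,TRUE,TRUE,TRUE,TRUE,5.1,5.8
12,TRUE,TRUE,TRUE,TRUE,5.9,5.5
13,FALSE,FALSE,TRUE,TRUE,5.3,5.0
14,FALSE,TRUE,TRUE,TRUE,6.0,5.6
15,FALSE,TRUE,TRUE,FALSE,5.7,6.2
16,FALSE,TRUE,TRUE,TRUE,5.2,5.9
17,FALSE,TRUE,TRUE,TRUE,5.5,5.3
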