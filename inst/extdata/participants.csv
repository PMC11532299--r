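age,gender,days
61,F,62
66,M,61
69,F,47
69,F,56
70,F,47
70,F,53
71,F,44
72,F,53
72,F,71
73,F,57
74,F,83
75,F,47
75,F,47
75,M,49
80,F,40
81,F,41
83,F,69
89,M,54
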