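variable,category,n,printed_pct
education,university,57065,27.3
education,high school,97456,46.5
education,junior high school,42856,20.5
education,primary,11948,5.7
citizenship,Italian,168807,79.7
citizenship,foreigner,43043,20.3
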