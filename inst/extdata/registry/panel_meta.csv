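panel,n_l_reported
MH,9
SWGDAM,11
Yfiler,17
PPY23,25
YfilerPlus,27
Ymax,29
full,41
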