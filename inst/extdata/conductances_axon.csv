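# Maximum ionic conductances [S/cm^2] for the four axon bands, shared by
# both cell presets. AH: axon hillock; SOCB: sodium channel band; NS: narrow
# segment; DA: distal axon. Channels not listed are absent from the axon
# (g_Ca = g_h = g_T = 0). Derived rows follow the same ratio rule as the
# soma/dendrite table.
channel,AH,SOCB,NS,DA
g_Na,0.8,2.4,0.9,0.8
g_K,0.6,0.8,0.6,0.6
g_KA,3*g_K,3*g_K,3*g_K,3*g_K
g_KCa,0.004*g_K,0.004*g_K,0.004*g_K,0.004*g_K
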