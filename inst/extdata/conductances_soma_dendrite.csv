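# Maximum ionic conductances [S/cm^2] for the A2 and D1 RGC presets,
# soma and dendrite regions. Entries "3*g_K" and "0.004*g_K" are derived
# from the g_K value of the same column at load time.
channel,A2.soma,A2.dendrite,D1.soma,D1.dendrite
g_Na,0.35,0.1,0.2,0.08
g_K,0.12,0.05,0.211,0.08
g_KA,3*g_K,3*g_K,3*g_K,3*g_K
g_KCa,0.004*g_K,0.004*g_K,0.004*g_K,0.004*g_K
g_Ca,0.137,0.05,0.013,0.01
g_h,0,0,0.0001,3e-5
g_T,0.004,0,0.0024,0.001
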