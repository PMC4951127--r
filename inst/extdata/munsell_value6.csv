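# Munsell chips at value 6, chroma 8: hue and xyY chromaticity coordinates
# (CIE 1931 2-degree observer; Y is the luminance factor on a 0-100 scale).
# 27 hues from 5Y to 10P in 2.5-hue steps; full-range stimulus set.
hue,value,chroma,x,y,Y
5Y,6,8,0.4426,0.4588,30.05
7.5Y,6,8,0.4321,0.4719,30.05
10Y,6,8,0.4201,0.4812,30.05
2.5GY,6,8,0.4006,0.4885,30.05
5GY,6,8,0.3772,0.4880,30.05
7.5GY,6,8,0.3418,0.4768,30.05
10GY,6,8,0.3116,0.4563,30.05
2.5G,6,8,0.2799,0.4239,30.05
5G,6,8,0.2612,0.3990,30.05
7.5G,6,8,0.2510,0.3829,30.05
10G,6,8,0.2420,0.3679,30.05
2.5BG,6,8,0.2332,0.3522,30.05
5BG,6,8,0.2236,0.3311,30.05
7.5BG,6,8,0.2171,0.3138,30.05
10BG,6,8,0.2116,0.2950,30.05
2.5B,6,8,0.2080,0.2789,30.05
5B,6,8,0.2088,0.2635,30.05
7.5B,6,8,0.2132,0.2537,30.05
10B,6,8,0.2189,0.2468,30.05
2.5PB,6,8,0.2274,0.2406,30.05
5PB,6,8,0.2360,0.2365,30.05
7.5PB,6,8,0.2505,0.2347,30.05
10PB,6,8,0.2637,0.2352,30.05
2.5P,6,8,0.2770,0.2372,30.05
5P,6,8,0.2905,0.2421,30.05
7.5P,6,8,0.3099,0.2502,30.05
10P,6,8,0.3259,0.2584,30.05
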