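# SYNTHETIC stand-in table for Munsell chips at value 5, chroma 8 (hues 5Y-10B,
# the cross-language discrimination spectrum). The authoritative renotation xyY
# for these chips is not bundled; chromaticities (x, y) are carried over from
# the value-6 chips of the same hue and chroma (renotation chromaticity shifts
# little across one value step), and the luminance factor is set to Y = 19.77,
# the Munsell value-5 luminance factor. Analyses use only the relative CIELAB
# delta-E spacing of these chips, which this approximation preserves.
hue,value,chroma,x,y,Y
5Y,5,8,0.4426,0.4588,19.77
7.5Y,5,8,0.4321,0.4719,19.77
10Y,5,8,0.4201,0.4812,19.77
2.5GY,5,8,0.4006,0.4885,19.77
5GY,5,8,0.3772,0.4880,19.77
7.5GY,5,8,0.3418,0.4768,19.77
10GY,5,8,0.3116,0.4563,19.77
2.5G,5,8,0.2799,0.4239,19.77
5G,5,8,0.2612,0.3990,19.77
7.5G,5,8,0.2510,0.3829,19.77
10G,5,8,0.2420,0.3679,19.77
2.5BG,5,8,0.2332,0.3522,19.77
5BG,5,8,0.2236,0.3311,19.77
7.5BG,5,8,0.2171,0.3138,19.77
10BG,5,8,0.2116,0.2950,19.77
2.5B,5,8,0.2080,0.2789,19.77
5B,5,8,0.2088,0.2635,19.77
7.5B,5,8,0.2132,0.2537,19.77
10B,5,8,0.2189,0.2468,19.77
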