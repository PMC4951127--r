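# Probed 2AFC stimulus pairs by language set. Pairs including the boundary
# chip are cross-category ("across"); step is in 2.5-hue-step units.
# Sets: greenblue (English boundary 7.5BG), wornol (Berinmo boundary 5GY),
# dumbuburou (Himba boundary 7.5GY). English Study 3 pairs (value 4 in the
# source) are listed as set greenblue_s3 and placed on the spectrum by hue.
set,chip_a,chip_b,step,label
greenblue,5B,2.5B,1,within
greenblue,5B,10BG,2,within
greenblue,5BG,2.5BG,1,within
greenblue,5BG,10G,2,within
greenblue,7.5BG,5BG,1,across
greenblue,2.5B,7.5BG,2,across
greenblue,10BG,7.5BG,1,across
greenblue,10BG,5BG,2,across
wornol,7.5Y,10Y,1,within
wornol,7.5Y,2.5GY,2,within
wornol,7.5GY,10GY,1,within
wornol,7.5GY,2.5G,2,within
wornol,5GY,7.5GY,1,across
wornol,10Y,5GY,2,across
wornol,2.5GY,5GY,1,across
wornol,2.5GY,7.5GY,2,across
dumbuburou,7.5Y,10Y,1,within
dumbuburou,7.5Y,2.5GY,2,within
dumbuburou,2.5GY,5GY,1,within
dumbuburou,10Y,5GY,2,within
dumbuburou,5GY,7.5GY,1,across
dumbuburou,2.5GY,7.5GY,2,across
dumbuburou,7.5GY,10GY,1,across
dumbuburou,7.5GY,2.5G,2,across
greenblue_s3,5B,2.5B,1,within
greenblue_s3,5B,10BG,2,within
greenblue_s3,2.5BG,10G,1,within
greenblue_s3,5BG,10G,2,within
greenblue_s3,10BG,7.5BG,1,across
greenblue_s3,2.5B,7.5BG,2,across
greenblue_s3,7.5BG,5BG,1,across
greenblue_s3,10BG,5BG,2,across
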