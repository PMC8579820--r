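# Andean-uplift epoch scheme: four time slices (Ma, oldest first).
# Dispersal multipliers default to 1 in every epoch; per-epoch
# area-by-area matrices may be supplied under 'multipliers'.
areas: [A, B, C, D]
boundaries: [50, 35, 15, 5, 0]
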