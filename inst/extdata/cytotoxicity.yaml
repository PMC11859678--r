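# Mean short-term oxaliplatin IC50 (uM) and thermal enhancement ratio (TER)
# for CMS4 colorectal cancer (mean over MDST8, COLO320, HUTU80 cell lines).
# TER is stored verbatim; it is not recomputed from the IC50 row because the
# tabulated TER is a mean of per-cell-line ratios, not the ratio of means.
temperature_c: [37, 38, 39, 40, 41, 42, 43]
ic50_uM:       [537.7, 353.7, 314.3, 311.3, 245.0, 229.7, 220.0]
ter:           [1.0, 1.43, 1.6, 1.63, 2.07, 2.13, 2.23]
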