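# Published per-region test-retest variability (TRV, %) and one-way ICC of
# VT estimated with the two-tissue compartment model in the first-in-human
# test-retest study of [18F]PF-06684511 (n = 8). The hippocampus TRV mean
# is not legible in the published table and is left missing.
region,trv_mean,trv_sd,icc
CERCX,12.4,11.0,0.644
CAU,20.5,9.8,0.291
PUT,16.1,7.7,0.487
THA,16.6,9.0,0.504
LFC,17.4,8.1,0.492
LTC,14.7,8.3,0.542
HIP,NA,7.1,0.548
LOC,15.5,8.9,0.565
LPC,17.6,9.0,0.599
ACC,15.1,8.8,0.418
PCC,15.8,8.4,0.443
AMG,19.6,9.3,0.417
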