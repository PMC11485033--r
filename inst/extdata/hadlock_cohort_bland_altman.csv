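formula,n,mean_diff,mean_ci_lo,mean_ci_hi,loa_lower,loa_lower_ci_lo,loa_lower_ci_hi,loa_upper,loa_upper_ci_lo,loa_upper_ci_hi
hadlock1,975,-45.67,-62.53,-28.82,-571.38,-600.2,-542.57,480.04,451.22,508.85
hadlock2,975,-68.75,-86.5,-50.99,-622.55,-652.9,-592.19,485.05,454.7,515.41
hadlock3,975,-66.21,-83.27,-49.15,-598.18,-627.34,-569.02,465.76,436.6,494.92
hadlock4,975,-35.11,-52.05,-18.16,-563.64,-592.62,-534.67,493.43,464.46,522.41
hadlock5,975,-83.57,-101.43,-65.72,-640.3,-670.81,-609.78,473.15,442.63,503.67
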