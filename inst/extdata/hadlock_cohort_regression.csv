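method,formula,intercept,intercept_ci_lo,intercept_ci_hi,slope,slope_ci_lo,slope_ci_hi
passing_bablok,hadlock1,44.269,21.647,63.094,1.006,0.998,1.014
passing_bablok,hadlock2,24.329,2.086,49.562,1.019,1.01,1.028
passing_bablok,hadlock3,36.538,15.362,57.192,1.019,1.011,1.028
passing_bablok,hadlock4,51.288,26.942,74.766,0.997,0.989,1.006
passing_bablok,hadlock5,86.621,62.962,107.897,1.005,0.996,1.014
theil_sen,hadlock1,176.274,123.851,225.369,0.953,0.933,0.973
theil_sen,hadlock2,168.493,113.667,227.786,0.961,0.952,0.97
theil_sen,hadlock3,168.057,114.073,220.383,0.965,0.956,0.973
theil_sen,hadlock4,181.344,133.51,234.811,0.945,0.936,0.953
theil_sen,hadlock5,243.371,176.4,296.891,0.944,0.935,0.954
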