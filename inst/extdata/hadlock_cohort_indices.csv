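formula,icc,icc_ci_lo,icc_ci_hi,icc_f,icc_df1,icc_df2,ccc,ccc_ci_lo,ccc_ci_hi,rho,c_b
hadlock1,0.95,0.94,0.96,40.79,974,578.67,0.951,0.945,0.957,0.952,0.998
hadlock2,0.94,0.93,0.95,37.09,974,257.68,0.945,0.938,0.951,0.948,0.996
hadlock3,0.95,0.94,0.96,40.28,974,254.91,0.949,0.943,0.956,0.952,0.997
hadlock4,0.95,0.94,0.96,40.03,974,794.83,0.950,0.944,0.956,0.951,0.999
hadlock5,0.94,0.93,0.95,36.20,974,145.20,0.942,0.935,0.949,0.946,0.995
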