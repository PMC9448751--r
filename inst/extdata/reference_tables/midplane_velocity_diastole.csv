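resolution_mm,mri_umax_ms,mri_umean_ms,cfd_umax_ms,cfd_umean_ms,printed_pct_diff_umax,printed_pct_diff_umean
4,0.06131,0.02599,0.1099,0.04859,56.76,60.59
3,0.07451,0.02902,0.09438,0.05193,23.53,56.61
2,0.09052,0.03700,0.09466,0.05067,4.471,31.18
1.5,0.1177,0.04063,0.1221,0.06024,3.670,38.88
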