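resolution_mm,mri_umax_ms,mri_umean_ms,cfd_umax_ms,cfd_umean_ms,printed_pct_diff_umax,printed_pct_diff_umean
4,0.6272,0.2646,0.9358,0.3396,39.49,24.85
3,0.6941,0.3958,0.8436,0.4016,19.44,1.476
2,0.7891,0.4707,0.9096,0.4777,14.19,1.476
1.5,0.7659,0.4910,0.9019,0.4289,16.31,13.49
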