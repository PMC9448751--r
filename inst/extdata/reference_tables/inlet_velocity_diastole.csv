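resolution_mm,mri_umax_ms,mri_umean_ms,cfd_umax_ms,cfd_umean_ms,printed_pct_diff_umax,printed_pct_diff_umean
4,0.1038,0.03710,0.08940,0.04660,14.91,22.70
3,0.09520,0.04420,0.09540,0.05480,0.2099,21.41
2,0.09600,0.05520,0.1020,0.06300,6.061,13.20
1.5,0.1087,0.06010,0.1127,0.06400,3.613,6.285
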