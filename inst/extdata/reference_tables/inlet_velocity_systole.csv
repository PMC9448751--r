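resolution_mm,mri_umax_ms,mri_umean_ms,cfd_umax_ms,cfd_umean_ms,printed_pct_diff_umax,printed_pct_diff_umean
4,1.018,0.2838,0.9988,0.3589,1.904,23.37
3,0.8052,0.3745,0.8209,0.4511,1.931,18.56
2,0.7986,0.4683,0.8010,0.5333,0.3001,12.98
1.5,0.7997,0.4835,0.8089,0.5248,1.144,8.192
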