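resolution_mm,mri_diameter_cm,cfd_diameter_cm
4,2.659,2.658
3,2.569,2.555
2,2.499,2.491
1.5,2.478,2.474
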