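{"seed":7,"synth":{"n_ms_3t":26,"n_nmo_3t":20,"n_ms_15t":26,"n_nmo_15t":20,"n_features":60,"n_discriminative":4,"effect_size":1.2,"n_scanner_shifted":12,"shift_size":1,"scale_shift":1,"block_correlation":0.3,"block_size":10,"volume_dim":[24,24,24],"spacing":[1,1,1],"lesion_count_range":[1,3],"lesion_radius_range_mm":[2.5,5],"lesion_texture_amplitude":40,"noise_sd":5,"clinical_null":false,"seed":7},"n_train":62,"alpha":0.05,"modality_cap":5,"fusion_cap":5,"sfs_trees":200,"sfs_folds":5,"sfs_repeats":3,"n_trees":500,"k":5,"B":500,"positive":"NMO"}
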