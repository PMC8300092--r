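study_id,n_obs,stage,forage_prop,dmi,fa,ee,ndf,ch4_mj,technique,subset
study_01,8,lactating,50,18.8,31.1,38.9,389,14.46,tracer,development
study_01,7,lactating,50,19.8,27.6,34.5,407,17.87,tracer,development
study_01,6,lactating,50,20.4,24.7,30.9,351,22.13,tracer,development
study_01,5,lactating,50,21.5,27.7,34.6,384,25.71,tracer,development
study_02,4,non-lactating,95,10.3,24.2,30.2,468,11,tracer,development
study_02,4,non-lactating,95,10.8,37.9,47.4,480,11.71,tracer,development
study_02,10,non-lactating,95,10.9,34.9,43.6,460,12.09,tracer,development
study_02,8,non-lactating,95,11.8,25.2,31.5,487,12.97,tracer,development
study_03,10,lactating,69,15,31.2,39,428,16,tracer,development
study_03,12,lactating,69,16.3,21.6,27,439,16.89,tracer,development
study_03,12,lactating,69,16.8,32.7,40.9,416,18,tracer,development
study_04,7,lactating,73,21.8,38.5,48.1,390,28.12,tracer,development
study_04,12,lactating,73,24.5,33.1,41.4,433,36,tracer,development
study_05,8,lactating,77,18.7,25.3,31.6,479,24.32,tracer,development
study_05,11,lactating,77,20.1,32.3,40.4,457,25.99,tracer,development
study_05,11,lactating,77,21.5,24.8,31,456,27.81,tracer,development
study_06,4,lactating,77,18,25.8,32.2,400,23,chamber,development
study_06,11,lactating,77,18.2,29.5,36.9,416,23.2,chamber,development
study_06,12,lactating,77,18.5,38.3,47.9,427,23.98,chamber,development
study_06,4,lactating,77,19.2,19.5,24.4,432,24.2,chamber,development
study_06,7,lactating,77,19.6,41.7,52.1,431,24.66,chamber,development
study_06,12,lactating,77,20,24.6,30.8,496,24.93,chamber,development
study_07,9,lactating,67,15.8,32.5,40.6,424,17.18,chamber,development
study_07,6,lactating,67,17.1,22,27.5,440,19.05,chamber,development
study_07,9,lactating,67,18.2,33.7,42.1,426,20.97,chamber,development
study_08,11,lactating,51,24.4,26.3,32.9,380,22,tracer,development
study_08,8,lactating,51,26.1,20.7,25.9,410,23.08,tracer,development
study_08,12,lactating,51,27.7,19.2,24,372,24.2,tracer,development
study_09,6,lactating,70,15.7,22.1,27.6,390,21,tracer,development
study_09,5,lactating,70,16.8,19.7,24.6,407,23.44,tracer,development
study_09,10,lactating,70,17.5,31.8,39.8,388,26.59,tracer,development
study_09,6,lactating,70,18.5,36.5,45.6,400,29.36,tracer,development
study_10,10,non-lactating,83,7.4,19.5,24.4,498,10,tracer,development
study_10,4,non-lactating,83,7.8,37.3,46.6,464,10.7,tracer,development
study_10,7,non-lactating,83,8.2,39.1,48.9,440,11.5,tracer,development
study_10,11,non-lactating,83,8.5,20.1,25.1,447,11.46,tracer,development
study_11,5,lactating,69,14.3,35,43.8,423,17,tracer,development
study_11,10,lactating,69,14.2,27.5,34.4,388,17.5,tracer,development
study_11,10,lactating,69,15,38.7,48.4,367,18.07,tracer,development
study_11,9,lactating,69,15.3,26.2,32.8,420,18.35,tracer,development
study_11,11,lactating,69,15.2,28.1,35.1,424,18.6,tracer,development
study_11,9,lactating,69,15.9,34.9,43.6,425,19,tracer,development
study_12,11,lactating,50,18.1,19.6,24.5,402,25,tracer,development
study_12,5,lactating,50,18.6,32.1,40.1,355,25.81,tracer,development
study_12,7,lactating,50,19.4,19.4,24.2,374,26.28,tracer,development
study_12,11,lactating,50,20.1,37.3,46.6,388,26.8,tracer,development
study_13,7,lactating,100,19.7,24.7,30.9,465,26,greenfeed,development
study_13,8,lactating,100,22.4,34.1,42.6,443,27.75,greenfeed,development
study_14,8,lactating,100,12.2,35.9,44.9,500,17,chamber,development
study_15,11,lactating,50,19,40,50,392,17.9,chamber,development
study_16,6,lactating,80,19.5,31.2,39,402,26.32,chamber,development
study_16,10,lactating,80,22.4,22.7,28.4,414,27.57,chamber,development
study_17,12,lactating,55,19.8,38.1,47.6,376,23,chamber,development
study_17,8,lactating,55,22.3,28.1,35.1,384,27,chamber,development
study_18,10,lactating,50,16,33,41.2,408,18.87,chamber,development
study_18,9,lactating,50,16.2,18.3,22.9,402,20.16,chamber,development
study_18,7,lactating,50,16.5,18.9,23.6,324,21.44,chamber,development
study_18,8,lactating,50,17.2,37.5,46.9,395,22.84,chamber,development
study_18,8,lactating,50,17.3,33.7,42.1,347,23.86,chamber,development
study_18,11,lactating,50,17.9,23.5,29.4,390,24.82,chamber,development
study_19,6,lactating,100,13.7,36.3,45.4,487,16.03,chamber,development
study_19,11,lactating,100,15.3,21.3,26.6,492,17.19,chamber,development
study_19,12,lactating,100,15.5,27.8,34.8,491,18.09,chamber,development
study_20,11,lactating,51,16.5,34.7,43.4,375,17,tracer,evaluation
study_20,8,lactating,51,17.8,37.8,47.2,366,18.99,tracer,evaluation
study_20,7,lactating,51,17.9,35.4,44.2,345,20.83,tracer,evaluation
study_20,6,lactating,51,18.9,18.5,23.1,378,23,tracer,evaluation
study_21,9,lactating,64,15.7,26.5,33.1,439,18.07,tracer,evaluation
study_21,6,lactating,64,16.3,36.3,45.4,411,18.44,tracer,evaluation
study_21,10,lactating,64,17,34.4,43,404,19.92,tracer,evaluation
study_21,11,lactating,64,17.3,41.4,51.7,423,20.2,tracer,evaluation
study_21,7,lactating,64,18.1,20.7,25.9,399,21.63,tracer,evaluation
study_21,9,lactating,64,18.1,30.2,37.8,387,22,tracer,evaluation
study_22,12,lactating,63,19.1,22.8,28.5,438,25.49,chamber,evaluation
study_22,8,lactating,63,19.5,21.4,26.7,446,25.65,chamber,evaluation
study_22,5,lactating,63,20.3,18.6,23.2,378,26.27,chamber,evaluation
study_22,4,lactating,63,21.4,28.7,35.9,374,27.51,chamber,evaluation
study_23,4,lactating,80,16,18.9,23.6,425,14.1,tracer,evaluation
study_23,12,lactating,80,18.2,19.6,24.5,469,22,tracer,evaluation
study_24,11,lactating,67,15.3,30.9,38.6,427,21,tracer,evaluation
study_24,12,lactating,67,16.8,35.8,44.7,429,25,tracer,evaluation
study_25,7,lactating,45,16.6,35.7,44.6,401,14.13,chamber,evaluation
study_25,6,lactating,45,17.7,28.8,36,362,14.69,chamber,evaluation
study_25,8,lactating,45,18.2,26.2,32.8,319,15.15,chamber,evaluation
study_25,4,lactating,45,18.9,36.7,45.9,374,16,chamber,evaluation
study_26,5,lactating,59,14,40.8,51,375,15,headhood,evaluation
study_26,9,lactating,59,15.9,36.5,45.6,376,22.94,headhood,evaluation
study_27,5,lactating,75,16.1,28.7,35.9,461,19.94,chamber,evaluation
study_27,7,lactating,75,17,30.8,38.5,418,21.22,chamber,evaluation
study_27,6,lactating,75,17.2,29.2,36.5,423,22.46,chamber,evaluation
study_27,12,lactating,75,18.1,39.3,49.1,448,23.94,chamber,evaluation
study_28,9,lactating,56,18.8,36.4,45.5,367,23,chamber,evaluation
study_28,4,lactating,56,19.5,18.5,23.1,353,22.78,chamber,evaluation
study_28,4,lactating,56,20.4,20.4,25.5,385,23,chamber,evaluation
study_28,8,lactating,56,20.9,32.8,41,390,22.7,chamber,evaluation
study_29,7,lactating,88,22.5,37.6,47,475,24,chamber,evaluation
study_29,10,lactating,88,23.1,35.1,43.9,474,25.05,chamber,evaluation
study_29,6,lactating,88,24.4,36,45,474,25.21,chamber,evaluation
study_29,6,lactating,88,25.1,24.3,30.4,442,25.79,chamber,evaluation
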