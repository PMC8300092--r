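ecm,silage,concentrate,conc_share_mean,conc_share_min,conc_share_max,dmi_mean,dmi_min,dmi_max,gei_mean,gei_min,gei_max
5000,1,I,11,0,37,15,12,17,279,232,312
5000,2,II,20,0,53,15,12,17,282,228,327
5000,3,II,25,0,50,16,12,18,292,233,340
5500,1,III,13,0,40,15,13,17,289,242,323
5500,2,III,16,0,38,16,13,17,292,245,323
5500,3,II,29,10,51,16,12,19,305,232,355
6000,1,III,14,0,40,16,14,18,300,255,331
6000,2,I,23,3,47,16,14,19,307,253,352
6000,3,II,32,9,52,17,14,20,319,252,368
6500,1,III,16,0,43,17,14,18,310,261,342
6500,2,III,22,4,47,17,14,19,316,268,350
6500,3,III,35,11,52,18,14,20,333,267,383
7000,1,II,21,1,53,17,15,19,324,276,359
7000,2,III,23,7,45,17,15,19,322,276,354
7000,3,II,39,16,55,19,15,21,347,279,398
7500,1,III,20,4,47,18,15,19,330,284,362
7500,2,I,32,15,53,18,15,21,345,278,394
7500,3,II,42,21,57,19,16,22,361,292,412
8000,1,III,22,7,49,18,16,20,340,294,371
8000,2,I,35,17,54,19,16,22,359,291,407
8000,3,II,45,26,59,20,16,23,376,307,427
8500,1,III,24,10,50,19,16,20,350,303,383
8500,2,I,37,18,55,20,16,22,372,308,422
8500,3,II,47,30,61,21,17,24,390,320,442
9000,1,III,26,12,52,19,17,21,360,313,393
9000,2,I,40,21,57,21,17,23,386,319,436
9000,3,II,50,34,63,22,18,24,405,334,457
9500,1,I,38,23,59,21,17,23,387,315,437
9500,2,I,43,25,59,21,18,24,400,332,451
9500,3,I,49,35,61,22,18,25,413,346,464
10000,1,I,39,23,60,21,18,24,401,332,452
10000,2,I,45,29,60,22,18,25,414,346,466
10000,3,I,52,38,62,23,19,25,427,358,477
10500,1,I,41,23,62,22,19,25,415,348,467
10500,2,I,48,32,61,23,19,25,429,359,480
10500,3,I,54,41,64,23,20,26,441,370,491
11000,1,I,43,25,63,23,19,26,429,358,480
11000,2,I,50,35,62,24,20,26,443,372,495
11000,3,I,57,43,67,24,20,27,454,381,504
11500,1,I,46,29,64,24,20,26,443,373,496
11500,2,I,52,38,63,24,21,27,457,388,510
11500,3,I,59,46,70,25,21,27,468,393,518
12000,1,I,48,32,65,24,21,27,458,387,511
12000,2,I,54,41,65,25,21,28,472,401,525
12000,3,I,59,48,68,26,21,28,484,404,537
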