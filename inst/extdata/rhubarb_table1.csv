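sample_id,origin,grade,surface_R,surface_G,surface_B,fracture_R,fracture_G,fracture_B,fracture_colored_R,fracture_colored_G,fracture_colored_B,powder_R,powder_G,powder_B,powder_colored_R,powder_colored_G,powder_colored_B
1,"Li, Gansu",2,176,141,42,162,142,78,125,38,34,195,148,38,203,85,26
2,"Li, Gansu",2,159,132,37,152,151,116,127,55,37,154,123,33,167,74,46
3,"Li, Gansu",2,181,150,47,166,151,100,147,52,31,175,135,27,196,83,35
4,"Li, Gansu",2,110,82,32,153,154,101,136,54,31,123,88,33,181,79,43
5,"Li, Gansu",3,90,72,37,202,181,112,198,79,34,144,113,43,216,120,44
6,"Li, Gansu",1,149,125,33,165,150,85,144,80,31,171,131,34,240,163,69
7,"Li, Gansu",1,102,86,47,105,91,42,44,42,44,118,90,31,173,85,46
8,"Dali, Yunnan",2,146,115,36,155,154,103,119,57,39,166,134,27,233,159,63
9,"Dali, Yunnan",3,84,70,37,115,107,70,80,42,43,116,87,29,233,172,92
10,"Dali, Yunnan",3,127,97,34,162,170,130,146,74,28,150,112,12,231,144,46
11,"Gansu",2,103,86,44,117,107,55,92,47,39,119,92,31,197,114,61
12,"Qinghai",1,128,95,28,126,93,31,94,47,33,132,101,21,143,64,45
13,"Xining, Qinghai",2,143,112,37,145,142,110,126,57,35,174,125,25,182,95,41
14,"Fengjie, Chongqing",3,104,84,33,112,109,47,57,53,39,103,81,36,180,101,49
15,"Xining, Qinghai",1,128,97,33,141,140,119,103,53,45,148,101,32,128,58,51
16,"Gansu",3,129,95,30,158,156,86,115,64,31,145,105,17,188,85,41
17,"Shanxi",2,142,114,42,124,111,77,132,50,44,170,125,41,181,89,43
18,"Gansu",3,108,92,53,114,110,42,88,56,36,108,79,27,166,83,46
19,"Tibet",1,106,83,44,127,120,61,101,54,47,126,86,18,156,58,42
20,"Shiqu, Sichuan",1,104,88,47,151,140,92,165,77,26,133,94,19,192,80,32
21,"Saichuan, Sichuan",1,113,95,49,156,115,33,112,44,46,158,112,21,200,91,33
22,"Changdu, Tibet",2,110,84,33,104,78,50,65,34,38,110,79,24,124,60,55
23,"Gansu",2,128,109,45,153,151,112,134,67,37,145,95,24,196,99,43
24,"Tibet",2,111,93,56,146,138,73,115,58,41,133,103,27,198,84,40
25,"Beichuan, Sichuan",2,82,65,34,139,138,86,105,59,42,111,81,25,166,65,44
26,"Liangshan, Sichuan",2,99,76,36,164,141,85,157,50,31,143,98,23,202,84,31
27,"Guizhou",3,109,85,31,117,100,35,67,47,43,109,76,25,185,89,44
28,"Yaan, Sichuan",2,123,91,26,166,164,135,154,62,33,151,110,22,198,74,36
29,"Changdu, Tibet",2,93,72,35,140,110,46,107,49,38,125,88,19,182,79,48
30,"Gansu",3,123,93,28,137,125,49,107,72,38,115,78,19,177,95,82
31,"Qinghai",1,121,82,22,128,111,39,96,53,42,120,87,24,158,70,51
32,"Sichuan",2,141,102,25,146,122,48,115,45,36,141,100,20,192,81,40
33,"Gansu",3,115,91,29,129,111,49,100,76,40,125,96,27,188,107,63
34,"Qinghai",3,102,87,38,108,105,56,64,56,37,123,102,25,213,143,87
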