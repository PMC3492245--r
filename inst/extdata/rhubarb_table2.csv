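condition,replicate,R,G,B
natural_light,1,116,102,57
natural_light,2,117,103,57
natural_light,3,117,103,57
natural_light,4,121,106,51
natural_light,5,122,106,57
natural_light,6,120,106,54
natural_light,7,119,105,54
natural_light,8,115,98,51
natural_light,9,123,100,49
natural_light,10,110,96,49
natural_light,11,87,77,42
natural_light,12,105,93,51
natural_light,13,110,98,53
natural_light,14,92,89,39
natural_light,15,96,75,41
lightbox,1,114,103,56
lightbox,2,114,103,56
lightbox,3,114,102,56
lightbox,4,112,100,54
lightbox,5,113,102,54
lightbox,6,111,101,55
lightbox,7,112,101,53
lightbox,8,112,100,54
lightbox,9,112,100,55
lightbox,10,112,101,55
lightbox,11,112,101,55
lightbox,12,114,102,55
lightbox,13,113,102,54
lightbox,14,112,101,54
lightbox,15,111,99,53
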