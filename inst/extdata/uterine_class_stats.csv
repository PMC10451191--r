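label,image_count,pixel_count
1,1603,13501701
2,869,659031
3,1090,10655977
4,201,39608
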