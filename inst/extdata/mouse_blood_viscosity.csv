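shear_rate_s-1,viscosity_mPa_s,source
2,18.94,"Vogel et al., C57Bl/6 mice"
5,13.33,"Vogel et al., C57Bl/6 mice"
11,10.52,"Vogel et al., C57Bl/6 mice"
23,8.07,"Vogel et al., C57Bl/6 mice"
45,6.31,"Vogel et al., C57Bl/6 mice"
90,5.96,"Vogel et al., C57Bl/6 mice"
225,4.91,"Vogel et al., C57Bl/6 mice"
450,3.85,"Vogel et al., C57Bl/6 mice"
0.7,13.36,"Windberger et al., BALB/c mice"
2.4,10.56,"Windberger et al., BALB/c mice"
94,4.87,"Windberger et al., BALB/c mice"
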