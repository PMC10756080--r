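"name","G","S","lambda_min","lambda_max","n_channels","harmonic"
"collagen_I",0.563357040244447,0.717868612201139,423,723,30,1
"collagen_II",0.475282066017773,0.771645848878979,423,723,30,1
"collagen_III",0.288288179993704,0.849895067855559,423,723,30,1
"collagen_IV",0.0887449895017068,0.884883280719358,423,723,30,1
"elastin",-0.307090938865434,0.814052755971566,423,723,30,1
"NADH",0.34056701196578,0.813619325780749,423,723,30,1
"FAD",-0.827145559904006,0.311612782297621,423,723,30,1
"melanin",-0.260149786769818,-0.616796757528499,423,723,30,1
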