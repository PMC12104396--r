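name,ic50_uM,ic50_sd_uM,ratio_printed
omeprazole,1.41,0.96,0.0288
lansoprazole,1.65,1.37,0.00332
pantoprazole,3.52,1.47,0.00124
rabeprazole,6.43,1.09,0.000635
ilaprazole,6.62,1.34,0.00224
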