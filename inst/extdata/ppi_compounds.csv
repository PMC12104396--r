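name,molecular_weight,cmax_ug_per_ml,fu_plasma,fu_incubation
omeprazole,345.42,1.12,0.01,0.02
lansoprazole,369.36,1.15,0.01,0.02
pantoprazole,383.37,2.5,0.01,0.02
rabeprazole,359.44,0.62,0.01,0.02
ilaprazole,366.44,0.45,0.01,0.02
ticlopidine,263.78,NA,0.01,0.02
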