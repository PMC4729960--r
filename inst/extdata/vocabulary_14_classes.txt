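mitochondrion
endoplasmic_reticulum
plasma_membrane
lysosome
peroxisome
endosome
actin_cytoskeleton
extracellular_matrix
nucleus_nonchromatin
chromatin
nuclear_lamina
proteasome
ribosome_40S
ribosome_60S
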