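label,acronym,name
1,CTX,cortex-like layer
2,WM,white-matter band
3,HPC,hippocampus-like block
4,TH,thalamus-like block
5,BS,brainstem-like block
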