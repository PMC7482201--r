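label,size
Domesday Book mean village size,150
C18th English villages mean size,160
Italian alpine communities 1250-1800,176
tribal societies community size,148
hunter-gatherer societies clan size,165
East Tennessee rural community,197
Hutterite farming communities,107
Nebraska Amish parishes,113
church congregations ideal size,200
company mean WW2 armies,180
academic research specialities,100-200
Twitter networks,100-200
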