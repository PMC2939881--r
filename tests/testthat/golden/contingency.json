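{"a":3,"b":2,"c":2,"d":1553,"labels":["ABSTRACT","FULLTEXT"],"log10_or":3.06623271912026,"half_width":1.29203893804541,"corrected":false,"ppv":0.6,"ppv_ci":[0.230724281276013,0.882379225767352],"fnr":0.00128617363344051}
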