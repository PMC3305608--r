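"term","beta","se","effect","ci_low","ci_high"
"A",1.98392349837707,0.148006239101618,7.27121569529947,5.44031302324804,9.71829699166904
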