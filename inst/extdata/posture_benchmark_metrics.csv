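class,precision,recall,f1
walking,0.9554,0.9374,0.9463
standing,0.8722,0.9163,0.8937
sitting,0.9406,0.9427,0.9416
fallen_on_ground,0.9354,0.8333,0.8814
lying_in_bed,0.8951,0.8878,0.8914
sleeping,0.8844,0.9047,0.8944
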