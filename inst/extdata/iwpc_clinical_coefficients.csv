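term,estimate
intercept,4.0376
age_decade,-0.2546
height_cm,0.0118
weight_kg,0.0134
race_asian,-0.6752
race_black_or_african_american,0.406
race_missing_or_mixed,0.0443
enzyme_inducer,1.2799
amiodarone,-0.5695
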