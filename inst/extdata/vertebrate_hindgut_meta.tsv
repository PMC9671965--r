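class	n_species	total_asvs	exclusive_asvs
fish	73	9567	8810
bird	216	19384	NA
mammal	208	35105	NA
reptile	52	NA	NA
amphibian	20	NA	NA
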