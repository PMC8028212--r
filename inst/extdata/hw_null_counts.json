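{
  "comment": "One realization of the Hardy-Weinberg null generator: n = 10000 individuals, two independent SNPs at minor allele frequency 0.45, independent binary phenotype with P(0) = 0.66. layer0/layer1 rows index the first SNP's genotype (0,1,2), columns the second SNP's genotype, for phenotype 0 and 1 respectively.",
  "layer0": [[619, 992, 439], [964, 1576, 614], [409, 674, 264]],
  "layer1": [[347, 527, 200], [496, 862, 332], [220, 328, 137]]
}
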