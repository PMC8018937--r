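# Synthetic cassette-exon gene for simulations and tests: two constitutive
# 300-bp exons flanking a 93-bp cassette (the length of the MAPT exon-10
# repeat cassette), on a toy chromosome.
gene_id: TOYMAPT
gene_name: MAPTlike
chrom: toy_chr
strand: "+"
isoforms:
  toy_3R:
    - [101, 400]    # E9
    - [701, 1000]   # E11
  toy_4R:
    - [101, 400]    # E9
    - [501, 593]    # E10, 93 bp cassette
    - [701, 1000]   # E11
events:
  TOY_4R:
    inclusion:
      - [400, 501]
      - [593, 701]
    exclusion: [400, 701]
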