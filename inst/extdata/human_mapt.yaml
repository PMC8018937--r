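# Human MAPT exon 9/10/11 cassette region (GRCh38, chr17, plus strand).
# Junction flank coordinates are the annotated exon edges; the OUTER edges
# of exons 9 and 11 are nominal placeholders (357 bp / 87 bp) since only the
# flanks enter any computation. Exon 10 (93 bp) is fully determined by its
# flanks.
gene_id: ENSG00000186868
gene_name: MAPT
chrom: chr17
strand: "+"
isoforms:
  MAPT_3R:
    - [45996308, 45996664]   # exon 9
    - [46014243, 46014329]   # exon 11
  MAPT_4R:
    - [45996308, 45996664]   # exon 9
    - [46010310, 46010402]   # exon 10 (93 bp cassette)
    - [46014243, 46014329]   # exon 11
events:
  MAPT_4R:
    inclusion:
      - [45996664, 46010310]   # X(9,10)
      - [46010402, 46014243]   # X(10,11)
    exclusion: [45996664, 46014243]   # X(9,11)
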