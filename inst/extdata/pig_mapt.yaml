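# Porcine MAPT exon 9/10/11 cassette region (Sscrofa11.1, Ensembl release 98).
# Junction flank coordinates (exon edges adjoining the introns) are the
# annotated positions; the OUTER edges of exons 9 and 11 are nominal
# placeholders (357 bp / 87 bp) since only the flanks enter any computation.
# Gene is on the minus strand; all coordinates ascending genomic order.
gene_id: ENSSSCG00000017311
gene_name: MAPT
chrom: chr12
strand: "-"
isoforms:
  MAPT_3R:
    - [17108675, 17108761]   # exon 11
    - [17122167, 17122523]   # exon 9
  MAPT_4R:
    - [17108675, 17108761]   # exon 11
    - [17112207, 17112299]   # exon 10 (93 bp cassette)
    - [17122167, 17122523]   # exon 9
events:
  MAPT_4R:
    inclusion:
      - [17112299, 17122167]   # X(9,10): exon 9 <- exon 10 junction
      - [17108761, 17112207]   # X(10,11): exon 10 <- exon 11 junction
    exclusion: [17108761, 17122167]   # X(9,11): skipping junction
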