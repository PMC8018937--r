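test_that("packaged MAPT fixtures carry the annotated junction flanks", {
  pig <- gene_model_fixture("pig_mapt")
  expect_identical(pig$gene_id, "ENSSSCG00000017311")
  expect_identical(pig$chrom, "chr12")
  expect_identical(pig$strand, "-")
  ev <- pig$events$MAPT_4R
  # printed high-to-low for the minus-strand gene; stored ascending
  expect_equal(ev$inclusion$donor, c(17112299, 17108761))
  expect_equal(ev$inclusion$acceptor, c(17122167, 17112207))
  expect_equal(ev$exclusion$donor, 17108761)
  expect_equal(ev$exclusion$acceptor, 17122167)

  hum <- gene_model_fixture("human_mapt")
  expect_identical(hum$gene_id, "ENSG00000186868")
  expect_identical(hum$chrom, "chr17")
  ev <- hum$events$MAPT_4R
  expect_equal(ev$inclusion$donor, c(45996664, 46010402))
  expect_equal(ev$inclusion$acceptor, c(46010310, 46014243))
  expect_equal(unlist(ev$exclusion), c(donor = 45996664, acceptor = 46014243))

  # the cassette exon is 93 bases in both species' models
  for (m in list(pig, hum)) {
    cas <- m$isoforms$MAPT_4R
    cas <- cas[!apply(cas, 1, function(r)
      any(m$isoforms$MAPT_3R$start == r[1])), , drop = FALSE]
    expect_equal(cas$end - cas$start + 1L, 93L)
  }
})

test_that("effective length is the union-exonic length", {
  m <- gene_model_fixture("toy")
  expect_equal(m$effective_length, 300L + 93L + 300L)
  # overlapping exons across isoforms are not double-counted
  m2 <- gene_model("G", "c", "+",
                   isoforms = list(a = rbind(c(1, 100)),
                                   b = rbind(c(51, 150))))
  expect_equal(m2$effective_length, 150L)
})

test_that("model validation rejects malformed structures", {
  expect_error(gene_model("G", "c", "+",
                          isoforms = list(a = rbind(c(10, 5)))),
               "start > end")
  expect_error(gene_model("G", "c", "+",
                          isoforms = list(a = rbind(c(1, 100), c(50, 150)))),
               "non-overlapping")
  expect_error(gene_model("G", "c", "+",
                          isoforms = list(a = rbind(c(1, 100), c(101, 150)))),
               "intronic base")
  # junction flank off any exon boundary
  expect_error(
    gene_model("G", "c", "+",
               isoforms = list(a = rbind(c(1, 100), c(201, 300))),
               events = list(e = cassette_event("e", rbind(c(99, 201)),
                                                c(100, 201)))),
    "not the last base")
  # exclusion junction must differ from inclusion junctions
  expect_error(cassette_event("e", rbind(c(100, 201)), c(100, 201)),
               "duplicates")
})

test_that("a single-isoform model with no events is valid", {
  m <- gene_model("G", "c", "+", isoforms = list(a = rbind(c(1, 100))))
  expect_s3_class(m, "gene_model")
  expect_length(m$events, 0)
})

test_that("model files round-trip through write and read", {
  for (fx in c("pig_mapt", "human_mapt", "toy")) {
    m <- gene_model_fixture(fx)
    path <- tempfile(fileext = ".yaml")
    write_gene_model(m, path)
    expect_equal(read_gene_model(path), m)
  }
})

test_that("the intron-boundary dialect shift lands on the exonic flanks", {
  m <- gene_model_fixture("toy")
  doc <- yaml::read_yaml(system.file("extdata", "toy_maptlike.yaml",
                                     package = "spliceq"))
  # rewrite events in intron-first/last convention (+1 / -1)
  doc$events$TOY_4R$inclusion <- lapply(doc$events$TOY_4R$inclusion,
                                        function(j) c(j[1] + 1, j[2] - 1))
  doc$events$TOY_4R$exclusion <- c(doc$events$TOY_4R$exclusion[1] + 1,
                                   doc$events$TOY_4R$exclusion[2] - 1)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, path)
  shifted <- read_gene_model(path, dialect_shift = TRUE)
  expect_equal(shifted$events$TOY_4R, m$events$TOY_4R)
})

test_that("loading reports malformed model files", {
  path <- tempfile()
  writeLines("gene_id: G\nchrom: c", path)
  expect_error(read_gene_model(path), "missing field")
  expect_error(read_gene_model(tempfile()), "not found")
})

test_that("flattening splits exons at isoform boundaries", {
  # no overlap: bins are the exons themselves
  m <- gene_model("G", "c", "+",
                  isoforms = list(a = rbind(c(1, 100), c(201, 300))))
  b <- flatten_exon_bins(m)
  expect_equal(b$start, c(1, 201))
  expect_equal(b$end, c(100, 300))
  expect_equal(b$contributing_isoforms, c("a", "a"))

  # shared prefix, one isoform extends further
  m <- gene_model("G", "c", "+",
                  isoforms = list(a = rbind(c(1, 150)),
                                  b = rbind(c(1, 100))))
  bins <- flatten_exon_bins(m)
  expect_equal(bins$start, c(1, 101))
  expect_equal(bins$end, c(100, 150))
  expect_equal(bins$contributing_isoforms, c("a,b", "a"))

  # cassette exon contributes only its own isoform
  bins <- flatten_exon_bins(gene_model_fixture("toy"))
  expect_equal(bins$contributing_isoforms[2], "toy_4R")
  expect_equal(bins[2, c("start", "end")],
               data.frame(start = 501L, end = 593L, row.names = 2L))
})

test_that("flattening matches the per-base labelling oracle", {
  for (seed in 1:20) {
    m <- random_gene_model(seed)
    got <- flatten_exon_bins(m)
    want <- oracle_flatten(m)
    expect_equal(got$start, want$start, info = paste("seed", seed))
    expect_equal(got$end, want$end, info = paste("seed", seed))
    sorted <- vapply(strsplit(got$contributing_isoforms, ","),
                     function(v) paste(sort(v), collapse = ","), "")
    expect_equal(sorted, want$contributing, info = paste("seed", seed))
    # disjoint and coverage: bins tile the exon union exactly
    expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    expect_equal(sum(got$end - got$start + 1L), m$effective_length)
  }
})

test_that("GFF3 exon lines plus an event table import as a model", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "toy_chr\ttest\texon\t101\t400\t.\t+\t.\tID=e1;Parent=tx_4R",
    "toy_chr\ttest\texon\t501\t593\t.\t+\t.\tID=e2;Parent=tx_4R",
    "toy_chr\ttest\texon\t701\t1000\t.\t+\t.\tID=e3;Parent=tx_4R",
    "toy_chr\ttest\texon\t101\t400\t.\t+\t.\tID=e4;Parent=tx_3R",
    "toy_chr\ttest\texon\t701\t1000\t.\t+\t.\tID=e5;Parent=tx_3R"), gff)
  ev <- tempfile(fileext = ".tsv")
  writeLines(c("event\trole\tchrom\tdonor\tacceptor\tstrand",
               "E10\tinclusion\ttoy_chr\t400\t501\t+",
               "E10\tinclusion\ttoy_chr\t593\t701\t+",
               "E10\texclusion\ttoy_chr\t400\t701\t+"), ev)
  m <- read_gene_model_gff(gff, ev, gene_id = "GFFTOY")
  expect_equal(m$effective_length, 693L)
  expect_equal(m$events$E10$inclusion$donor, c(400, 593))
  expect_equal(m$events$E10$exclusion$acceptor, 701)
})
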