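sam_line <- function(qname, pos, cigar, flag = 0, rname = "chr1") {
  paste(qname, flag, rname, pos, 255, cigar, "*", 0, 0, "*", "*",
        sep = "\t")
}

test_that("a skip produces the junction between flanking aligned bases", {
  tab <- extract_junctions(sam_line("r1", 101, "30M100N45M"))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$donor, 130L)      # last aligned base before the skip
  expect_equal(tab$acceptor, 231L)   # first aligned base after it
  expect_equal(tab$count, 1L)
  expect_equal(attr(tab, "library_size"), 1L)
})

test_that("a record with two skips increments both junctions", {
  tab <- extract_junctions(sam_line("r1", 101, "20M50N30M50N25M"))
  expect_equal(tab$donor, c(120L, 200L))
  expect_equal(tab$acceptor, c(171L, 251L))
  expect_equal(tab$count, c(1L, 1L))
  expect_equal(attr(tab, "library_size"), 1L)
})

test_that("min_anchor suppresses junctions with short flanking blocks", {
  lines <- c(sam_line("r1", 101, "5M100N70M"),
             sam_line("r2", 101, "30M100N45M"))
  expect_equal(sum(extract_junctions(lines, min_anchor = 1)$count), 2L)
  tab <- extract_junctions(lines, min_anchor = 6)
  expect_equal(tab$count, 1L)      # r1's 5-base anchor fails
  expect_equal(attr(tab, "library_size"), 2L)  # but r1 is still counted
  # the middle block of a double-skip read anchors both junctions
  tab <- extract_junctions(sam_line("r3", 101, "30M50N4M50N30M"),
                           min_anchor = 5)
  expect_equal(nrow(tab), 0L)
})

test_that("unmapped, secondary and supplementary records are skipped", {
  lines <- c(sam_line("r1", 101, "30M100N45M"),
             sam_line("r2", 101, "30M100N45M", flag = 4),     # unmapped
             sam_line("r3", 101, "30M100N45M", flag = 256),   # secondary
             sam_line("r4", 101, "30M100N45M", flag = 2048))  # supplementary
  tab <- extract_junctions(lines)
  expect_equal(tab$count, 1L)
  expect_equal(attr(tab, "library_size"), 1L)
})

test_that("insertions, deletions and soft clips shift junctions correctly", {
  # 10M 2I 10M: insertion consumes no reference; donor at 101+20-1=120
  tab <- extract_junctions(sam_line("r1", 101, "10M2I10M100N10M"))
  expect_equal(tab$donor, 120L)
  expect_equal(tab$acceptor, 221L)
  # deletion consumes reference: 10M 5D 10M spans 25 bases
  tab <- extract_junctions(sam_line("r2", 101, "10M5D10M100N10M"))
  expect_equal(tab$donor, 125L)
  # soft clip before the alignment does not move POS
  tab <- extract_junctions(sam_line("r3", 101, "5S10M100N10M"))
  expect_equal(tab$donor, 110L)
})

test_that("malformed records are reported by name; empty input is empty", {
  expect_error(extract_junctions(sam_line("badrec", 101, "30M100Q45M")),
               "badrec")
  expect_error(extract_junctions("r1\t0\tchr1\t101"), "malformed")
  tab <- extract_junctions(character())
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "library_size"), 0L)
})

test_that("extraction agrees with an independent junction caller", {
  cfg <- sim_config(n_reads = 500, read_length = 100, seed = 42)
  sim <- simulate_reads(cfg)
  got <- extract_junctions(sim$sam, min_anchor = 1)
  want <- ga_junction_counts(sim$sam)
  expect_same_junctions(got, want)
})

test_that("junction tables round-trip through plain TSV", {
  tab <- extract_junctions(c(sam_line("r1", 101, "30M100N45M"),
                             sam_line("r2", 101, "30M100N45M")))
  path <- tempfile(fileext = ".tsv")
  write_junction_table(tab, path)
  back <- read_junction_table(path, "plain_tsv", library_size = 2)
  expect_equal(back$count, tab$count)
  expect_equal(back$donor, tab$donor)
  # headerless variant parses too
  writeLines("chr12\t17112299\t17122167\t+\t57", path)
  tab2 <- read_junction_table(path, "plain_tsv")
  expect_equal(tab2$count, 57)
  expect_equal(tab2$donor, 17112299L)
})

test_that("the star_sj dialect shifts intron boundaries onto exonic flanks", {
  path <- tempfile(fileext = ".tab")
  # intron 401..500 on +, 35 unique reads
  writeLines("toy_chr\t401\t500\t1\t1\t1\t35\t4\t20", path)
  tab <- read_junction_table(path, "star_sj")
  expect_equal(tab$donor, 400L)
  expect_equal(tab$acceptor, 501L)
  expect_equal(tab$count, 35)
  expect_equal(tab$strand, "+")
})

test_that("the jcounts dialect reads featureCounts-style junction tables", {
  path <- tempfile(fileext = ".txt")
  writeLines(c(paste("PrimaryGene", "SecondaryGenes", "Site1_chr",
                     "Site1_location", "Site1_strand", "Site2_chr",
                     "Site2_location", "Site2_strand", "s1.bam",
                     sep = "\t"),
               "TOYMAPT\tNA\ttoy_chr\t400\t+\ttoy_chr\t701\t+\t12"), path)
  tab <- read_junction_table(path, "jcounts")
  expect_equal(tab$donor, 400L)
  expect_equal(tab$acceptor, 701L)
  expect_equal(tab$count, 12)
  writeLines(c("chr1\tx\t10\t+\t5", "chr1\ty\t20\t+\t7"), path)
  expect_error(read_junction_table(path, "plain_tsv"), "integer")
})

test_that("depth normalization is per million and leaves raw counts alone", {
  tab <- junction_counts(data.frame(chrom = "c", donor = 1L,
                                    acceptor = 10L, strand = "*",
                                    count = 50))
  expect_equal(normalize_depth(tab, 1e6)$normalized, 50)
  expect_equal(normalize_depth(tab, 2e6)$normalized, 25)
  expect_equal(normalize_depth(tab, 2e6)$count, 50)
  expect_error(normalize_depth(tab), "library_size")
  expect_error(normalize_depth(tab, 0), "library_size")
})

test_that("usage is identical before and after depth normalization", {
  jt <- simulate_junction_table(sim_config(n_reads = 20000, seed = 11))
  ev <- gene_model_fixture("toy")$events$TOY_4R
  raw <- compute_usage(jt$table, ev)
  norm <- compute_usage(normalize_depth(jt$table, 20000), ev)
  expect_equal(raw$usage_percent, norm$usage_percent)
})
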