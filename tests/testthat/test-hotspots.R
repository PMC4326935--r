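toy_assignments <- function(classes) {
  out <- data.frame(mirna_id = names(classes), class = unname(classes),
                    stringsAsFactors = FALSE)
  class(out) <- c("class_assignment", "data.frame")
  out
}

toy_loci <- function(df) {
  df$strand <- if (is.null(df$strand)) "+" else df$strand
  class(df) <- c("mirna_loci", "data.frame")
  df
}

test_that("GFF3 and cytoband round-trip through the annotation loader", {
  sim <- generate_dataset(simulation_config(panel_size = 60, seed = 2))
  loci <- generate_annotation(sim$truth,
                              hotspot_spec = list(list(band = "14q32.31",
                                                       class = "age_constant",
                                                       n = 6L)),
                              n_extra_loci = 5L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  map <- withr::local_tempfile(fileext = ".txt")
  write_mirna_gff3(loci, gff)
  write_cytoband_map(loci, map)
  back <- load_annotation(gff, cytoband_map = map)
  key <- function(d) {
    d$start <- as.numeric(d$start); d$end <- as.numeric(d$end)
    d[order(d$mirna_id, d$chromosome, d$start),
      c("mirna_id", "chromosome", "start", "end", "strand", "cytoband")]
  }
  a <- key(as.data.frame(loci)); b <- key(as.data.frame(back))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a)
  # multi-locus miRNAs come back with one row per placement
  expect_gt(nrow(back), length(unique(back$mirna_id)))
})

test_that("flat TSV annotations load with explicit cytobands", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tchromosome\tstart\tend\tstrand\tcytoband",
               "miR-410\t14\t101532249\t101532328\t+\t14q32.31",
               "let-7a\t9\t96938239\t96938318\t+\t9q22.32",
               "let-7a\t11\t122017230\t122017301\t-\t11q24.1"), path)
  loci <- load_annotation(path)
  expect_equal(nrow(loci), 3L)
  expect_equal(sum(loci$mirna_id == "let-7a"), 2L)  # one miRNA, two loci
  expect_equal(loci$cytoband[loci$chromosome == "14"], "14q32.31")
  writeLines(c("mirna_id\tchromosome\tstart\tend\tstrand",
               "m1\t1\t500\t100\t+"), path)
  expect_error(load_annotation(path), "malformed coordinate")
})

test_that("empty annotations are allowed", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mirna_id\tchromosome\tstart\tend\tstrand\tcytoband", path)
  expect_equal(nrow(load_annotation(path)), 0L)
})

test_that("band tables count distinct miRNAs once per band", {
  cls <- toy_assignments(c(m1 = "age_constant", m2 = "up_in_adult",
                           m3 = "nonexpressed"))
  loci <- toy_loci(data.frame(
    mirna_id = c("m1", "m1", "m2", "m3"),
    chromosome = c("9", "11", "9", "1"),
    start = c(100, 200, 300, 400), end = c(180, 280, 380, 480),
    cytoband = c("9q22.32", "11q24.1", "9q22.32", "1p36.33"),
    stringsAsFactors = FALSE))
  bt <- chromosome_class_table(cls, loci)
  # m1 on two bands + m2 on one = 3 placements for 2 detectable miRNAs;
  # the nonexpressed m3 is excluded from band-level analysis
  expect_equal(sum(bt$n_mirna), 3L)
  expect_equal(attr(bt, "genome_total"), 2L)
  expect_equal(sum(attr(bt, "band_sizes")), 3L)
  expect_false("1p36.33" %in% bt$cytoband)
  # duplicate placements of the same miRNA on one band count once
  loci2 <- toy_loci(rbind(as.data.frame(loci),
                          data.frame(mirna_id = "m2", chromosome = "9",
                                     start = 900, end = 980, strand = "+",
                                     cytoband = "9q22.32")))
  bt2 <- chromosome_class_table(cls, loci2)
  expect_equal(sum(bt2$n_mirna), 3L)
})

test_that("hot spots require strictly more than the cluster threshold", {
  classes <- setNames(rep(c("age_constant", "up_in_adult"), c(10, 8)),
                      sprintf("m%02d", 1:18))
  bands <- c(rep("14q32.31", 6), rep("2q13", 4),   # 6-member cluster
             rep("9q22.32", 5), rep("4q25", 3))    # 5-member: below rule
  loci <- toy_loci(data.frame(
    mirna_id = names(classes), chromosome = sub("[pq].*", "", bands),
    start = seq(100, by = 1000, length.out = 18),
    end = seq(180, by = 1000, length.out = 18),
    cytoband = bands, stringsAsFactors = FALSE))
  bt <- chromosome_class_table(toy_assignments(classes), loci)
  hs <- find_hotspots(bt, cluster_threshold = 5)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$cytoband, "14q32.31")
  expect_equal(hs$n_members, 6L)
  expect_equal(hs$prop_band, 1)
  expect_equal(hs$prop_genome, 10 / 18)
  # output invariant to input row order
  shuf <- loci[sample(nrow(loci)), ]
  class(shuf) <- class(loci)
  hs2 <- find_hotspots(chromosome_class_table(toy_assignments(classes), shuf),
                       cluster_threshold = 5)
  expect_equal(hs2, hs)
})

test_that("coordinate conventions are 1-based inclusive end to end", {
  # a 1 bp locus at the very first base of a band must land in that band
  map <- withr::local_tempfile()
  writeLines(c("chr5\t0\t1000\tp15.33\tgneg",
               "chr5\t1000\t2000\tp15.2\tgneg"), map)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tchromosome\tstart\tend\tstrand",
               "m1\t5\t1\t1\t+",        # first base of p15.33
               "m2\t5\t1000\t1000\t+",  # last base of p15.33
               "m3\t5\t1001\t1001\t+"), # first base of p15.2
             path)
  loci <- load_annotation(path, cytoband_map = map)
  expect_equal(loci$cytoband, c("5p15.33", "5p15.33", "5p15.2"))
})
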