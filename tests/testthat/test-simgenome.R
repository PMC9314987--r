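test_that("a configuration without events or divergence reproduces A exactly", {
  cfg <- quiet_cfg(7, c(chr1 = 20000, chr2 = 15000))
  p <- simulate_pair(cfg)
  expect_identical(as.character(p$a), as.character(p$b))
  expect_equal(nrow(p$truth), 0L)
})

test_that("identical seeds give byte-identical assemblies and truth", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 1e5, chrX = 1e5),
                    x_name = "chrX", sv_length_range = c(1000, 5000),
                    sd_counts = c("A>A" = 0, "A>X" = 1, "X>A" = 1),
                    sd_length_range = c(2000, 4000))
  p1 <- simulate_pair(cfg)
  p2 <- simulate_pair(cfg)
  expect_identical(as.character(p1$a), as.character(p2$a))
  expect_identical(as.character(p1$b), as.character(p2$b))
  expect_identical(p1$truth, p2$truth)
})

test_that("a planted 5 kb deletion shortens the B chromosome to 95 kb", {
  cfg <- quiet_cfg(3, c(chr1 = 100000),
                   planted_events = data.frame(kind = "DEL", chrom = "chr1",
                                               start = 40000, length = 5000))
  p <- simulate_pair(cfg)
  expect_equal(length(p$b[["chr1"]]), 95000L)
  expect_equal(p$truth$kind, "DEL")
  expect_equal(p$truth$length, 5000L)
})

test_that("chromosome lengths obey event conservation", {
  cfg <- sim_config(seed = 21, chrom_lengths = c(chr1 = 3e5, chr2 = 3e5,
                                                 chrX = 3e5),
                    x_name = "chrX", sv_length_range = c(1000, 5000),
                    sd_length_range = c(2000, 5000), ngap_count = 3)
  p <- simulate_pair(cfg)
  tr <- p$truth
  dels <- sum(tr$length[tr$kind == "DEL"])
  ins <- sum(tr$length[tr$kind == "INS"])
  dups <- sum(tr$length[tr$kind == "DUP"])
  sds <- sum(tr$length[tr$kind == "SD" & tr$role == "derived"])
  expect_equal(sum(as.numeric(Biostrings::width(p$b))),
               sum(as.numeric(Biostrings::width(p$a))) -
                 dels + ins + dups + sds)
})

test_that("planted events are mutually disjoint in the truth table", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chr1 = 5e5, chr2 = 5e5,
                                                chrX = 5e5),
                    x_name = "chrX", sv_length_range = c(1000, 6000),
                    ngap_count = 4)
  p <- simulate_pair(cfg)
  a_side <- p$truth[p$truth$role %in% c("sv", "parent"), ]
  for (chrom in unique(a_side$chrom)) {
    iv <- a_side[a_side$chrom == chrom, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1)
      expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  }
})

test_that("derived SD copies carry the extra mutation load", {
  # binomial(10000, 0.02) oracle: mismatches within 3 SD of 200
  cfg <- sim_config(seed = 13, chrom_lengths = c(chr2 = 2e5, chrX = 2e5),
                    x_name = "chrX", background_divergence = 0,
                    derived_extra_divergence = 0.02,
                    sv_rates = c(DEL = 0, INS = 0, DUP = 0, INV = 0),
                    sd_counts = c("A>A" = 0, "A>X" = 0, "X>A" = 1),
                    sd_length_range = c(10000, 10000), ngap_count = 0)
  p <- simulate_pair(cfg)
  par <- p$truth[p$truth$role == "parent", ]
  der <- p$truth[p$truth$role == "derived", ]
  s_par <- as.character(Biostrings::subseq(p$a[[par$chrom]],
                                           par$start + 1, par$end))
  s_der <- as.character(Biostrings::subseq(p$b[[der$chrom]],
                                           der$start + 1, der$end))
  d <- sum(strsplit(s_par, "")[[1]] != strsplit(s_der, "")[[1]])
  sd3 <- 3 * sqrt(10000 * 0.02 * 0.98)
  expect_true(abs(d - 200) <= sd3)
  expect_equal(par$direction, "X>A")
  expect_equal(par$chrom, "chrX")
})

test_that("N-gap runs appear only in assembly A and are recoverable", {
  cfg <- quiet_cfg(4, c(chr1 = 2e5), ngap_count = 3)
  p <- simulate_pair(cfg)
  runs_a <- n_runs(p$a)
  runs_b <- n_runs(p$b)
  expect_equal(nrow(runs_a), 3L)
  expect_equal(nrow(runs_b), 0L)
  expect_true(all(runs_a$end > runs_a$start))
})

test_that("truth tables round-trip through write_truth/read_truth", {
  cfg <- sim_config(seed = 2, chrom_lengths = c(chr1 = 2e5, chrX = 2e5),
                    x_name = "chrX", sv_length_range = c(1000, 4000),
                    sd_counts = c("A>A" = 0, "A>X" = 1, "X>A" = 1),
                    sd_length_range = c(2000, 4000))
  p <- simulate_pair(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(p$truth, path)
  back <- read_truth(path)
  expect_equal(back, p$truth, ignore_attr = TRUE)
  # SD events contribute a parent and a derived row sharing the id
  sd_rows <- back[back$kind == "SD", ]
  expect_true(all(table(sd_rows$event_id) == 2L))
  # empty truth gives a header-only file that reads back empty
  write_truth(p$truth[0, ], path)
  expect_equal(nrow(read_truth(path)), 0L)
  expect_equal(length(readLines(path)), 1L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(1, c(100, 200)), "named")
  expect_error(sim_config(1, c(chr1 = 0)), "> 0")
  expect_error(sim_config(1, c(chr1 = 1e5), x_name = "chrZ"), "x_name")
  expect_error(sim_config(1, c(chr1 = 1e5), background_divergence = 0.05,
                          derived_extra_divergence = 0.02),
               "background_divergence")
  expect_error(sim_config(1, c(chr1 = 1e5),
                          sd_counts = c("A>X" = 1, "X>A" = 0, "A>A" = 0)),
               "x_name")
  # impossible placement density errors out rather than looping forever
  cfg <- quiet_cfg(1, c(chr1 = 30000),
                   sv_rates = c(DEL = 400, INS = 0, DUP = 0, INV = 0),
                   sv_length_range = c(2000, 2000))
  expect_error(simulate_pair(cfg), "too small")
})
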