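empty_assembly <- function(names, len = 10e6) {
  # continuity checks need sequences; use short all-A stand-ins and
  # coordinates that stay inside them
  Biostrings::DNAStringSet(stats::setNames(rep(strrep("A", 100000), length(names)),
                                           names))
}

test_that("a chain junction advancing on A only is a deletion", {
  syn <- make_synteny(c("chr1", "chr1"), c(0, 53000), c(50000, 90000), "+",
                      c("chr1", "chr1"), c(0, 50000), c(50000, 87000),
                      chain_id = 1)
  asm <- empty_assembly("chr1")
  svs <- classify_svs(syn, syn, asm, asm)
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$sv_type, "DEL")
  expect_equal(svs$length, 3000)
  expect_equal(svs$a_start, 50000)
  expect_equal(svs$a_end, 53000)
})

test_that("a chain junction advancing on B only is an insertion", {
  syn <- make_synteny(c("chr1", "chr1"), c(0, 50000), c(50000, 90000), "+",
                      c("chr1", "chr1"), c(0, 54000), c(50000, 94000),
                      chain_id = 1)
  asm <- empty_assembly("chr1")
  svs <- classify_svs(syn, syn, asm, asm)
  expect_equal(svs$sv_type, "INS")
  expect_equal(svs$length, 4000)
  expect_equal(svs$b_start, 50000)
  expect_equal(svs$b_end, 54000)
})

test_that("a minus segment between plus neighbours is one inversion", {
  syn <- make_synteny(c("chr1", "chr1", "chr1"),
                      c(0, 40000, 50000), c(40000, 50000, 90000),
                      c("+", "-", "+"),
                      c("chr1", "chr1", "chr1"),
                      c(0, 40000, 50000), c(40000, 50000, 90000),
                      chain_id = c(1, 2, 1))
  asm <- empty_assembly("chr1")
  svs <- classify_svs(syn, syn, asm, asm)
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$sv_type, "INV")
  expect_equal(svs$length, 10000)
  expect_equal(svs$a_start, 40000)
  expect_equal(svs$a_end, 50000)
})

test_that("simultaneous gaps on both sides split into one DEL plus one INS", {
  syn <- make_synteny(c("chr1", "chr1"), c(0, 53000), c(50000, 90000), "+",
                      c("chr1", "chr1"), c(0, 52000), c(50000, 92000),
                      chain_id = 1)
  asm <- empty_assembly("chr1")
  svs <- classify_svs(syn, syn, asm, asm)
  expect_setequal(svs$sv_type, c("DEL", "INS"))
  expect_equal(sort(svs$length), c(2000, 3000))
})

test_that("classification recovers the exact planted set at zero divergence", {
  cfg <- sim_config(seed = 33, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                    background_divergence = 0,
                    sv_rates = c(DEL = 3, INS = 3, DUP = 2, INV = 2),
                    sv_length_range = c(1500, 6000),
                    sd_counts = c("A>A" = 0, "A>X" = 0, "X>A" = 0),
                    ngap_count = 0)
  p <- simulate_pair(cfg)
  bl <- anchor_chain_align(p$a, p$b)
  svs <- filter_svs(classify_svs(one_to_one_map(bl), bl, p$a, p$b))
  tr <- p$truth[p$truth$role == "sv", ]
  expect_equal(nrow(svs), nrow(tr))
  ev <- evaluate_sv_calls(svs, p$truth)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)
  # type-by-chromosome tallies agree exactly
  expect_equal(table(svs$sv_type, svs$chrom), table(tr$kind, tr$chrom))
})

test_that("the length filter keeps 1 kb events and removes shorter ones", {
  svs <- asmpair:::new_sv_table(data.frame(
    sv_type = c("DEL", "DEL", "INS"), chrom = "chr1",
    a_start = c(0, 5000, 10000), a_end = c(999, 6000, 10000),
    b_start = c(0, 5000, 9000), b_end = c(0, 5000, 10500),
    length = c(999, 1000, 1500), continuous = c(TRUE, TRUE, FALSE)))
  kept <- filter_svs(svs, min_len = 1000, require_continuous = FALSE)
  expect_equal(kept$length, c(1000, 1500))
  kept2 <- filter_svs(svs, min_len = 1000, require_continuous = TRUE)
  expect_equal(kept2$length, 1000)
  # idempotent
  expect_equal(filter_svs(kept2), kept2)
})

test_that("events overlapping N runs are flagged discontinuous and filtered", {
  cfg <- quiet_cfg(44, c(chr1 = 3e5), ngap_count = 3,
                   ngap_length_range = c(1200, 2500))
  p <- simulate_pair(cfg)
  bl <- anchor_chain_align(p$a, p$b)
  svs <- classify_svs(one_to_one_map(bl), bl, p$a, p$b)
  # each N run surfaces as a DEL+INS junction pair, all discontinuous
  expect_true(nrow(svs) > 0)
  expect_true(all(!svs$continuous))
  expect_equal(nrow(filter_svs(svs)), 0L)
})

test_that("per-chromosome counting is exact and rejects unknown chromosomes", {
  chroms <- data.frame(chrom = c("chr1", "chrX"), length = c(2e6, 1e6),
                       is_x = c(FALSE, TRUE))
  empty <- asmpair:::new_sv_table()
  tab <- count_by_chromosome(empty, chroms)
  expect_true(all(as.matrix(tab[, c("DEL", "INS", "DUP", "INV")]) == 0))
  svs <- asmpair:::new_sv_table(data.frame(
    sv_type = c("DEL", "DEL", "DEL", "INV"),
    chrom = c("chr1", "chr1", "chr1", "chrX"),
    a_start = 0, a_end = 1000, b_start = 0, b_end = 0,
    length = 1000, continuous = TRUE))
  tab2 <- count_by_chromosome(svs, chroms)
  expect_equal(tab2$DEL, c(3L, 0L))
  expect_equal(tab2$INV, c(0L, 1L))
  expect_equal(sum(as.matrix(tab2[, c("DEL", "INS", "DUP", "INV")])),
               nrow(svs))
  bad <- svs; bad$chrom[1] <- "chr9"
  expect_error(count_by_chromosome(bad, chroms), "unknown")
})

test_that("SV tables export to TSV and symbolic-ALT VCF", {
  cfg <- sim_config(seed = 12, chrom_lengths = c(chr1 = 2e5),
                    background_divergence = 0,
                    sv_rates = c(DEL = 5, INS = 5, DUP = 0, INV = 5),
                    sv_length_range = c(1500, 4000),
                    sd_counts = c("A>A" = 0, "A>X" = 0, "X>A" = 0),
                    ngap_count = 0)
  p <- simulate_pair(cfg)
  bl <- anchor_chain_align(p$a, p$b)
  svs <- filter_svs(classify_svs(one_to_one_map(bl), bl, p$a, p$b))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sv_tsv(svs, tsv)
  expect_equal(read_sv_tsv(tsv), svs, ignore_attr = TRUE)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(svs, p$a, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(svs))
  expect_true(all(grepl("SVTYPE=(DEL|INS|DUP|INV)", body)))
  # VCF positions are 1-based
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  expect_true(all(pos >= 1))
})
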