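test_that("two copies sharing one anchor locus form a single SD pair", {
  # two A-chromosome loci align to one B anchor locus (anchor on the
  # target side here, mirroring a copies-in-query comparison)
  bl <- make_blocks(query_name = c("chr1", "chr5"),
                    query_start = c(10000, 60000),
                    query_end = c(11500, 61500), strand = "+",
                    target_name = c("chrX_anchor", "chrX_anchor"),
                    target_start = c(5000, 5000),
                    target_end = c(6500, 6500))
  pr <- find_many_to_one(bl, anchor_side = "target")
  expect_equal(nrow(pr), 1L)
  expect_setequal(c(pr$copy1_chrom, pr$copy2_chrom), c("chr1", "chr5"))
  expect_equal(pr$length, 1500)
  expect_equal(attr(pr, "copy_side"), "query")
})

test_that("blocks below 1 kb or with weak anchor overlap are not paired", {
  short <- make_blocks(query_name = c("chr1", "chr5"),
                       query_start = c(10000, 60000),
                       query_end = c(10900, 60900), strand = "+",
                       target_name = c("t", "t"),
                       target_start = c(5000, 5000),
                       target_end = c(5900, 5900))
  expect_equal(nrow(find_many_to_one(short, anchor_side = "target")), 0L)
  weak <- make_blocks(query_name = c("chr1", "chr5"),
                      query_start = c(10000, 60000),
                      query_end = c(11500, 61500), strand = "+",
                      target_name = c("t", "t"),
                      target_start = c(5000, 6000),
                      target_end = c(6500, 7500))
  # anchor overlap 500 of 1500 falls below the 0.8 rule
  expect_equal(nrow(find_many_to_one(weak, anchor_side = "target")), 0L)
})

test_that("an n-copy family expands to all pairwise combinations", {
  bl <- make_blocks(query_name = c("chr1", "chr3", "chr5"),
                    query_start = c(1e4, 5e4, 9e4),
                    query_end = c(1e4, 5e4, 9e4) + 2000, strand = "+",
                    target_name = "t", target_start = 5000,
                    target_end = 7000)
  pr <- find_many_to_one(bl, anchor_side = "target")
  expect_equal(nrow(pr), choose(3, 2))
  expect_equal(length(unique(pr$family_id)), 1L)
})

test_that("boundary and internal SD classes follow chain context", {
  # one long chain covering chr1 [0, 200kb) on the copy side
  syn <- make_synteny("a1", 0, 200000, "+", "chr1", 0, 200000, chain_id = 1)
  base <- data.frame(family_id = 1L, anchor_chrom = "a1",
                     anchor_start = 0, anchor_end = 2000,
                     copy1_chrom = "chr1", copy1_start = 50000,
                     copy1_end = 52000,
                     copy2_chrom = "chr1", copy2_start = 100000,
                     copy2_end = 102000,
                     copy1_block_identity = 1, copy2_block_identity = 1,
                     length = 2000, stringsAsFactors = FALSE)
  attr(base, "copy_side") <- "target"
  # both copies >= 10 kb inside the chain: internal
  r <- classify_sd(base, syn)
  expect_equal(r$sd_class, "iSD")
  expect_equal(r$chain_span1, 200000)
  # a copy ending 200 bp from the chain end: boundary
  nearend <- base
  nearend$copy2_start <- 197800; nearend$copy2_end <- 199800
  expect_equal(classify_sd(nearend, syn)$sd_class, "bSD")
  # a copy entirely outside any chain: boundary by definition
  outside <- base
  outside$copy2_chrom <- "chr9"
  r3 <- classify_sd(outside, syn)
  expect_equal(r3$sd_class, "bSD")
  expect_equal(r3$chain_span2, 0)
})

test_that("internal SDs resolve by synteny length, boundary SDs by identity", {
  syn <- make_synteny(c("a1", "a2"), c(0, 0), c(200000, 50000), "+",
                      c("chr1", "chr2"), c(0, 0), c(200000, 50000),
                      chain_id = c(1, 2))
  pr <- data.frame(family_id = 1L, anchor_chrom = "a1",
                   anchor_start = 0, anchor_end = 2000,
                   copy1_chrom = "chr1", copy1_start = 50000,
                   copy1_end = 52000,
                   copy2_chrom = "chr2", copy2_start = 20000,
                   copy2_end = 22000,
                   copy1_block_identity = 1, copy2_block_identity = 1,
                   length = 2000, stringsAsFactors = FALSE)
  attr(pr, "copy_side") <- "target"
  pr <- classify_sd(pr, syn)
  expect_equal(pr$sd_class, "iSD")
  expect_equal(c(pr$chain_span1, pr$chain_span2), c(200000, 50000))
  # chain spans 200,000 vs 50,000: copy1 parental
  dummy <- Biostrings::DNAStringSet()  # synteny route needs no sequence
  r <- resolve_parent(pr, dummy, dummy, x_name = NA)
  expect_equal(r$parental, "copy1")
  expect_equal(r$parent_chrom, "chr1")
})

test_that("the boundary-SD identity rule picks the closer copy above 90%", {
  set.seed(77)
  anchor <- random_dna_string(3000)
  mutate_frac <- function(s, frac) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), round(frac * length(v)))
    for (p in at) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  near <- mutate_frac(anchor, 0.02)   # ~0.98 identity
  far <- mutate_frac(anchor, 0.07)    # ~0.93 identity
  asm_anchor <- Biostrings::DNAStringSet(c(a1 = anchor))
  asm_copy <- Biostrings::DNAStringSet(c(chr1 = near, chr2 = far))
  pr <- data.frame(family_id = 1L, anchor_chrom = "a1",
                   anchor_start = 0, anchor_end = 3000,
                   copy1_chrom = "chr1", copy1_start = 0, copy1_end = 3000,
                   copy2_chrom = "chr2", copy2_start = 0, copy2_end = 3000,
                   copy1_block_identity = NA, copy2_block_identity = NA,
                   length = 3000, sd_class = "bSD",
                   chain_span1 = 0, chain_span2 = 0,
                   stringsAsFactors = FALSE)
  attr(pr, "copy_side") <- "target"
  r <- resolve_parent(pr, asm_copy, asm_anchor, x_name = NA)
  expect_equal(r$parental, "copy1")
  expect_gt(r$copy1_identity, r$copy2_identity)
  # both identities at or below the threshold: unresolved
  faint1 <- mutate_frac(anchor, 0.12)
  faint2 <- mutate_frac(anchor, 0.13)
  asm_faint <- Biostrings::DNAStringSet(c(chr1 = faint1, chr2 = faint2))
  r2 <- resolve_parent(pr, asm_faint, asm_anchor, x_name = NA)
  expect_equal(r2$parental, "unresolved")
  expect_equal(r2$direction, "unresolved")
})

test_that("direction categories count on the derived chromosome and conserve", {
  chroms <- data.frame(chrom = c("chr2", "chr3", "chr7", "chrX"),
                       length = 1e6, is_x = c(FALSE, FALSE, FALSE, TRUE))
  pr <- data.frame(
    family_id = 1:3,
    parental = c("copy1", "copy1", "unresolved"),
    parent_chrom = c("chrX", "chr2", NA),
    derived_chrom = c("chr3", "chr7", NA),
    direction = c("X>A", "A>A", "unresolved"),
    stringsAsFactors = FALSE)
  r <- categorize_direction(pr, chroms)
  expect_equal(r$counts[r$counts$chrom == "chr3", "X>A"], 1L)
  expect_equal(r$counts[r$counts$chrom == "chr7", "A>A"], 1L)
  expect_equal(sum(as.matrix(r$counts[, c("A>A", "A>X", "X>A", "X>X")])) +
                 r$unresolved, r$total)
})

test_that("genes are listed when they intersect the derived copy", {
  pr <- data.frame(family_id = 1L, parental = "copy1",
                   copy1_chrom = "chrX", copy1_start = 1000,
                   copy1_end = 5000,
                   copy2_chrom = "chr3", copy2_start = 20000,
                   copy2_end = 24000, stringsAsFactors = FALSE)
  genes <- data.frame(chrom = c("chr3", "chrX", "chr3"),
                      start = c(21000, 2000, 50000),
                      end = c(22000, 3000, 51000),
                      gene_id = c("inside", "on_parent", "far"))
  r <- genes_in_derived(pr, genes)
  expect_equal(r[[1]], "inside")
  expect_equal(attr(r, "all_genes"), "inside")
  # empty annotation gives empty lists
  r2 <- genes_in_derived(pr, genes[0, ])
  expect_equal(r2[[1]], character(0))
  # unknown chromosomes are skipped with a warning
  expect_warning(r3 <- genes_in_derived(pr, genes, known_chroms = "chr3"),
                 "unknown")
  expect_equal(r3[[1]], "inside")
})

test_that("simulated duplications without extra divergence stay unresolved", {
  cfg <- sim_config(seed = 55,
                    chrom_lengths = c(chr1 = 3e5, chr2 = 3e5, chrX = 3e5),
                    x_name = "chrX", background_divergence = 0,
                    derived_extra_divergence = 1e-9,
                    sv_rates = c(DEL = 0, INS = 0, DUP = 0, INV = 0),
                    sd_counts = c("A>A" = 2, "A>X" = 2, "X>A" = 2),
                    sd_length_range = c(2000, 6000), ngap_count = 0)
  p <- simulate_pair(cfg)
  bl <- anchor_chain_align(p$a, p$b)
  syn <- one_to_one_map(bl)
  pr <- find_many_to_one(bl)
  pr <- pr[pr$copy1_chrom != pr$copy2_chrom, , drop = FALSE]
  pr <- resolve_parent(classify_sd(pr, syn), p$b, p$a, x_name = "chrX")
  # identical copies carry no direction signal; the resolver must not
  # guess confidently in either direction
  expect_true(all(pr$parental == "unresolved"))
})
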