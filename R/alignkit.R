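BLOCK_COLS <- c("query_name", "query_len", "query_start", "query_end",
                "strand", "target_name", "target_len", "target_start",
                "target_end", "matches", "block_length", "identity",
                "mapq", "tags")

#' Construct and validate a table of alignment blocks
#'
#' An alignment block is one gapless-chained local alignment between the
#' two assemblies. Coordinates are 0-based half-open and, as in PAF, query
#' coordinates always refer to the forward strand of the query.
#'
#' @param df data frame carrying at least `query_name`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target_name`, `target_len`,
#'   `target_start`, `target_end`, `matches`, `block_length`.
#' @return validated data frame of class `alignment_blocks`.
#' @export
alignment_blocks <- function(df) {
  if (!"mapq" %in% names(df)) df$mapq <- 255L
  if (!"tags" %in% names(df)) df$tags <- ""
  df$identity <- ifelse(df$block_length > 0, df$matches / df$block_length, 0)
  missing <- setdiff(BLOCK_COLS, names(df))
  if (length(missing))
    stop("missing block columns: ", paste(missing, collapse = ", "))
  df <- df[, unique(c(BLOCK_COLS, names(df)))]
  validate_blocks(df)
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

validate_blocks <- function(df) {
  with(df, {
    if (any(query_start >= query_end) || any(target_start >= target_end))
      stop("block validation: start must be < end on both sides")
    if (any(query_start < 0) || any(target_start < 0))
      stop("block validation: negative coordinates")
    if (any(query_end > query_len) || any(target_end > target_len))
      stop("block validation: interval exceeds sequence length")
    if (any(!strand %in% c("+", "-")))
      stop("block validation: strand must be '+' or '-'")
    if (any(matches < 0) || any(matches > block_length))
      stop("block validation: matches must lie in [0, block_length]")
    shorter <- pmin(query_end - query_start, target_end - target_start)
    if (any(block_length < shorter))
      stop("block validation: block_length below aligned span")
  })
  invisible(df)
}

#' Align two assemblies by unique-anchor chaining
#'
#' A minimal whole-genome local aligner adequate for low-divergence
#' assembly pairs: exact k-mers that are unique in the query genome (and
#' occur at most `max_target_hits` times in the target genome) serve as
#' anchors, which are greedily chained while the anchor diagonal stays
#' within `gap_tol` and consecutive anchors are at most `max_anchor_gap`
#' apart on the query. Chains split at strand flips, diagonal jumps and
#' anchor deserts (N-runs, rearrangement breakpoints), so the retained
#' blocks end at event boundaries. Identity is computed from a gap-free
#' column comparison over the chained span (gap columns from residual
#' diagonal drift count as mismatches). Target multiplicity above one lets
#' duplicated loci surface as many-to-one alignments.
#'
#' @param assembly_a,assembly_b named [Biostrings::DNAStringSet] objects;
#'   A is the query side, B the target side.
#' @param k anchor length (11--32).
#' @param min_block minimum aligned span (bp, both sides) to report.
#' @param gap_tol tolerated anchor diagonal drift within a block (bp).
#' @param max_anchor_gap maximum query distance between consecutive
#'   anchors of one block (bp).
#' @param max_target_hits maximum target-genome multiplicity of an anchor
#'   k-mer.
#' @return an [alignment_blocks()] data frame.
#' @export
anchor_chain_align <- function(assembly_a, assembly_b, k = 21L,
                               min_block = 1000L, gap_tol = 100L,
                               max_anchor_gap = 500L, max_target_hits = 4L) {
  stopifnot(is(assembly_a, "DNAStringSet"), is(assembly_b, "DNAStringSet"))
  if (length(assembly_a) == 0L || length(assembly_b) == 0L)
    return(alignment_blocks(cbind(empty_block_df(),
                                  data.frame(n_anchors = numeric(0)))[0, ]))
  if (k < 11L || k > 32L) stop("k must be between 11 and 32")
  if (k > min(Biostrings::width(assembly_a), Biostrings::width(assembly_b)))
    stop("k larger than the shortest chromosome")
  qn <- names(assembly_a); tn <- names(assembly_b)
  raw <- cpp_anchor_chain(as.character(assembly_a), as.character(assembly_b),
                          as.integer(k), as.integer(max_target_hits),
                          as.integer(gap_tol), as.integer(max_anchor_gap),
                          as.integer(min_block))
  df <- data.frame(
    query_name = qn[raw$qc + 1L],
    query_len = Biostrings::width(assembly_a)[raw$qc + 1L],
    query_start = raw$qstart, query_end = raw$qend,
    strand = c("+", "-")[raw$strand + 1L],
    target_name = tn[raw$tc + 1L],
    target_len = Biostrings::width(assembly_b)[raw$tc + 1L],
    target_start = raw$tstart, target_end = raw$tend,
    matches = raw$matches, block_length = raw$block_length,
    n_anchors = raw$n_anchors,
    stringsAsFactors = FALSE)
  df <- df[order(df$query_name, df$query_start, df$target_name,
                 df$target_start), , drop = FALSE]
  rownames(df) <- NULL
  alignment_blocks(df)
}

empty_block_df <- function() {
  data.frame(query_name = character(), query_len = numeric(),
             query_start = numeric(), query_end = numeric(),
             strand = character(), target_name = character(),
             target_len = numeric(), target_start = numeric(),
             target_end = numeric(), matches = numeric(),
             block_length = numeric(), identity = numeric(),
             mapq = integer(), tags = character(),
             stringsAsFactors = FALSE)
}

#' Pairwise identity by banded global alignment
#'
#' Aligns two sequences globally under unit match/mismatch/gap scoring and
#' returns identity = matches / alignment columns (gap columns count).
#' Among minimum-edit-cost alignments the one with most matches (then
#' fewest columns) is scored, which makes the value deterministic and
#' symmetric in its arguments. For long sequences the dynamic program is
#' restricted to a diagonal band; `band = NULL` uses the full matrix up to
#' 2000 bp and `|length difference| + 64` beyond that.
#'
#' @param seq1,seq2 character scalars or [Biostrings::DNAString] objects.
#' @param band band half-width in bp, or `NULL` for automatic choice.
#' @param details return matches/columns/cost alongside the identity?
#' @return identity fraction in `[0, 1]`; with `details = TRUE` a list.
#' @export
pairwise_identity <- function(seq1, seq2, band = NULL, details = FALSE) {
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (length(s1) != 1L || length(s2) != 1L || !nzchar(s1) || !nzchar(s2))
    stop("pairwise_identity requires two non-empty sequences")
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (is.null(band)) {
    band <- if (max(n1, n2) <= 2000L) max(n1, n2) else
      abs(n1 - n2) + 64L
  }
  v <- cpp_banded_identity(s1, s2, as.integer(band))
  if (details)
    list(identity = v[1], matches = v[2], columns = v[3], cost = v[4])
  else v[1]
}

#' Read or write alignment blocks in PAF format
#'
#' Standard 12-column PAF plus tags. On read, mapping quality and tag
#' columns are preserved opaquely; on write, blocks produced by this
#' package carry mapq 255 and an `id:f:` identity tag. Fields are
#' validated against the alignment-block invariants and malformed lines
#' are reported with their line number.
#'
#' @param path file path.
#' @param blocks an [alignment_blocks()] data frame.
#' @return `read_paf` returns an [alignment_blocks()] data frame;
#'   `write_paf` returns `path` invisibly.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(alignment_blocks(empty_block_df()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 12L)
      stop(sprintf("malformed PAF line %d: expected >= 12 columns, got %d",
                   i, length(p)))
    num <- suppressWarnings(as.numeric(p[c(2:4, 7:12)]))
    if (anyNA(num))
      stop(sprintf("malformed PAF line %d: non-numeric coordinate field", i))
    if (!p[5] %in% c("+", "-"))
      stop(sprintf("malformed PAF line %d: bad strand '%s'", i, p[5]))
    rows[[i]] <- data.frame(
      query_name = p[1], query_len = num[1], query_start = num[2],
      query_end = num[3], strand = p[5], target_name = p[6],
      target_len = num[4], target_start = num[5], target_end = num[6],
      matches = num[7], block_length = num[8], mapq = as.integer(num[9]),
      tags = paste(p[-(1:12)], collapse = "\t"),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  tryCatch(alignment_blocks(df),
           error = function(e) stop("PAF validation error: ",
                                    conditionMessage(e), call. = FALSE))
}

#' @rdname read_paf
#' @export
write_paf <- function(blocks, path) {
  validate_blocks(blocks)
  tags <- ifelse(nzchar(blocks$tags), blocks$tags,
                 sprintf("id:f:%.6f", blocks$identity))
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%s",
                   blocks$query_name, as.integer(blocks$query_len),
                   as.integer(blocks$query_start),
                   as.integer(blocks$query_end), blocks$strand,
                   blocks$target_name, as.integer(blocks$target_len),
                   as.integer(blocks$target_start),
                   as.integer(blocks$target_end),
                   as.integer(blocks$matches),
                   as.integer(blocks$block_length),
                   as.integer(blocks$mapq), tags)
  writeLines(lines, path)
  invisible(path)
}
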