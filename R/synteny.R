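#' Build the one-to-one synteny map from alignment blocks
#'
#' Drops blocks below the identity threshold, resolves overlaps so that no
#' two retained blocks overlap by more than `overlap_frac` of the shorter
#' block on either assembly (higher-scoring blocks win; ties broken by
#' match count, then span, then target name and coordinate), and greedily
#' chains the survivors into collinear, strand-consistent chains. Each
#' block is annotated with its `chain_id` and `chain_span`, the sum of
#' block lengths in its chain (the "synteny length" used for parental
#' calls on internal segmental duplications).
#'
#' @param blocks an [alignment_blocks()] data frame.
#' @param min_identity minimum identity for the one-to-one map.
#' @param overlap_frac overlap fraction (of the shorter block) above which
#'   two blocks conflict.
#' @param max_chain_gap maximum coordinate gap (bp, either assembly)
#'   bridged within one chain.
#' @param slack tolerated overlap (bp) between consecutive chain blocks.
#' @return the retained blocks with `chain_id` and `chain_span` columns,
#'   class `synteny_blocks`.
#' @export
one_to_one_map <- function(blocks, min_identity = 0.90,
                           overlap_frac = 0.5, max_chain_gap = 100000L,
                           slack = 50L) {
  validate_blocks(blocks)
  df <- as.data.frame(blocks)[blocks$identity >= min_identity, , drop = FALSE]
  if (nrow(df) == 0L) {
    df$chain_id <- integer(0); df$chain_span <- numeric(0)
    class(df) <- c("synteny_blocks", "data.frame")
    return(df)
  }
  ord <- order(-df$matches, -pmax(df$query_end - df$query_start,
                                  df$target_end - df$target_start),
               df$target_name, df$target_start, df$query_name,
               df$query_start)
  df <- df[ord, , drop = FALSE]
  ## resolve overlaps in score order: the lower-scoring block is trimmed
  ## back to its non-overlapping residue (a duplication overlaps a
  ## higher-scoring block on one side only); blocks whose residue
  ## vanishes -- e.g. a derived copy competing for the same locus -- are
  ## dropped, so no two retained blocks overlap substantially on either
  ## assembly
  min_residue <- max(200L, 4L * slack)
  kept <- list()
  for (i in seq_len(nrow(df))) {
    cand <- df[i, ]
    qspan <- cand$query_end - cand$query_start
    head_trim <- 0; tail_trim <- 0; drop <- FALSE
    for (k in kept) {
      ## query-side overlap
      if (cand$query_name == k$query_name) {
        os <- max(cand$query_start, k$query_start)
        oe <- min(cand$query_end, k$query_end)
        if (oe - os > 0) {
          if (k$query_start > cand$query_start &&
              k$query_end < cand$query_end) {
            ## kept block nested inside the candidate
            if (oe - os >= overlap_frac *
                min(qspan, k$query_end - k$query_start)) drop <- TRUE
          } else if (k$query_start <= cand$query_start) {
            head_trim <- max(head_trim, oe - cand$query_start)
          } else {
            tail_trim <- max(tail_trim, cand$query_end - os)
          }
        }
      }
      ## target-side overlap, expressed as query head/tail trims
      if (cand$target_name == k$target_name) {
        os <- max(cand$target_start, k$target_start)
        oe <- min(cand$target_end, k$target_end)
        if (oe - os > 0) {
          if (k$target_start > cand$target_start &&
              k$target_end < cand$target_end) {
            if (oe - os >= overlap_frac *
                min(cand$target_end - cand$target_start,
                    k$target_end - k$target_start)) drop <- TRUE
          } else if (k$target_start <= cand$target_start) {
            amt <- oe - cand$target_start
            if (cand$strand == "+") head_trim <- max(head_trim, amt)
            else tail_trim <- max(tail_trim, amt)
          } else {
            amt <- cand$target_end - os
            if (cand$strand == "+") tail_trim <- max(tail_trim, amt)
            else head_trim <- max(head_trim, amt)
          }
        }
      }
      if (drop) break
    }
    if (drop) next
    if (head_trim + tail_trim > 0) {
      new_qs <- cand$query_start + head_trim
      new_qe <- cand$query_end - tail_trim
      if (new_qe - new_qs < min_residue) next
      frac <- (new_qe - new_qs) / qspan
      if (cand$strand == "+") {
        cand$target_start <- cand$target_start + head_trim
        cand$target_end <- cand$target_end - tail_trim
      } else {
        cand$target_start <- cand$target_start + tail_trim
        cand$target_end <- cand$target_end - head_trim
      }
      cand$query_start <- new_qs; cand$query_end <- new_qe
      if (cand$target_end <= cand$target_start) next
      cand$matches <- round(cand$matches * frac)
      cand$block_length <- round(cand$block_length * frac)
      cand$identity <- ifelse(cand$block_length > 0,
                              cand$matches / cand$block_length, 0)
    }
    kept[[length(kept) + 1L]] <- cand
  }
  df <- do.call(rbind, kept)
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(blocks)[0, , drop = FALSE]
    df$chain_id <- integer(0); df$chain_span <- numeric(0)
    class(df) <- c("synteny_blocks", "data.frame")
    return(df)
  }
  df <- df[order(df$query_name, df$target_name, df$query_start,
                 df$target_start), , drop = FALSE]
  rownames(df) <- NULL

  ## greedy chaining within (query chromosome, target chromosome)
  df$chain_id <- NA_integer_
  next_chain <- 1L
  grp <- paste(df$query_name, df$target_name)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    open <- list()  # each: list(id, strand, qend, tstart, tend)
    for (i in idx) {
      ## attach to the compatible open chain with the smallest query gap
      best <- NULL; best_gap <- Inf
      for (ci in seq_along(open)) {
        ch <- open[[ci]]
        if (ch$strand != df$strand[i]) next
        qgap <- df$query_start[i] - ch$qend
        if (ch$strand == "+") {
          tgap <- df$target_start[i] - ch$tend
        } else {
          tgap <- ch$tstart - df$target_end[i]
        }
        ## forward continuation, or a query rewind with a continuous
        ## target (the downstream block of a tandem duplication re-reads
        ## the duplicated query interval)
        ok_forward <- qgap >= -slack && qgap <= max_chain_gap &&
          tgap >= -slack && tgap <= max_chain_gap
        ok_rewind <- qgap < -slack && qgap >= -max_chain_gap &&
          abs(tgap) <= slack
        if (!ok_forward && !ok_rewind) next
        if (abs(qgap) < best_gap) { best <- ci; best_gap <- abs(qgap) }
      }
      if (!is.null(best)) {
        ch <- open[[best]]
        df$chain_id[i] <- ch$id
        open[[best]]$qend <- max(ch$qend, df$query_end[i])
        open[[best]]$tstart <- df$target_start[i]
        open[[best]]$tend <- max(ch$tend, df$target_end[i])
        if (ch$strand == "-") open[[best]]$tstart <- df$target_start[i]
      } else {
        df$chain_id[i] <- next_chain
        open[[length(open) + 1L]] <- list(id = next_chain,
                                          strand = df$strand[i],
                                          qend = df$query_end[i],
                                          tstart = df$target_start[i],
                                          tend = df$target_end[i])
        next_chain <- next_chain + 1L
      }
    }
  }
  span <- tapply(df$block_length, df$chain_id, sum)
  df$chain_span <- as.numeric(span[as.character(df$chain_id)])
  class(df) <- c("synteny_blocks", "data.frame")
  df
}

# map a query coordinate through a block to target coordinates
map_through_block <- function(block, q) {
  if (block$strand == "+") block$target_start + (q - block$query_start)
  else block$target_end - (q - block$query_start)
}

#' Gap-filling statistics for N-runs in orthologous regions
#'
#' A gap (maximal N-run in assembly A) counts toward the denominator if
#' and only if its flanking `flank` bp on both sides lie inside one-to-one
#' synteny blocks; it counts as filled if both flanks map to the same
#' chromosome of assembly B through blocks of the same chain and the
#' implied spanning interval on B contains no N.
#'
#' @param gaps data frame `chrom`, `start`, `end` (0-based half-open) of
#'   N-runs in assembly A, e.g. from [n_runs()].
#' @param assembly_b the second assembly ([Biostrings::DNAStringSet]).
#' @param synteny a [one_to_one_map()] result.
#' @param flank flank width (bp) that must lie inside one-to-one blocks
#'   for the gap to be "in an orthologous region".
#' @return list with `per_chrom` (chrom, total, filled), `total_gaps`,
#'   `filled_gaps` and `fill_rate`.
#' @export
gap_fill_stats <- function(gaps, assembly_b, synteny, flank = 1000L) {
  total <- integer(0); filled <- integer(0)
  res <- data.frame(chrom = gaps$chrom, in_ortho = FALSE, filled = FALSE)
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    cand <- synteny[synteny$query_name == g$chrom, , drop = FALSE]
    covers <- function(s, e) which(cand$query_start <= s & cand$query_end >= e)
    li <- covers(g$start - flank, g$start)
    ri <- covers(g$end, g$end + flank)
    if (length(li) == 0L || length(ri) == 0L) next
    res$in_ortho[i] <- TRUE
    ## prefer a same-chain pair of covering blocks
    pair <- NULL
    for (a in li) for (b in ri) {
      if (cand$chain_id[a] == cand$chain_id[b] &&
          cand$target_name[a] == cand$target_name[b]) {
        pair <- c(a, b); break
      }
    }
    if (is.null(pair)) next
    bl <- cand[pair[1], ]; br <- cand[pair[2], ]
    tl <- map_through_block(bl, g$start)
    tr <- map_through_block(br, g$end)
    span <- sort(c(tl, tr))
    if (span[2] <= span[1]) next
    seq_b <- Biostrings::subseq(assembly_b[[bl$target_name]],
                                span[1] + 1L, span[2])
    nn <- Biostrings::countPattern("N", seq_b, fixed = TRUE)
    if (nn == 0L) res$filled[i] <- TRUE
  }
  res <- res[res$in_ortho, , drop = FALSE]
  per <- if (nrow(res)) {
    agg <- stats::aggregate(cbind(total = in_ortho, filled = filled) ~ chrom,
                            data = res, FUN = sum)
    agg
  } else data.frame(chrom = character(), total = integer(),
                    filled = integer())
  list(per_chrom = per,
       total_gaps = sum(per$total),
       filled_gaps = sum(per$filled),
       fill_rate = if (sum(per$total) > 0)
         sum(per$filled) / sum(per$total) else NA_real_)
}

#' Per-chromosome gapless-length ratio between two assemblies
#'
#' For every chromosome present in both assemblies, reports the ratio of
#' non-N length in assembly B to non-N length in assembly A. Chromosomes
#' present in only one assembly, or entirely N in A, are reported as
#' missing (`NA`) with a warning.
#'
#' @param assembly_a,assembly_b named [Biostrings::DNAStringSet] objects.
#' @return data frame `chrom`, `a_gapless`, `b_gapless`, `l_r`.
#' @export
gapless_length_ratio <- function(assembly_a, assembly_b) {
  chroms <- union(names(assembly_a), names(assembly_b))
  nonN <- function(set, chrom) {
    if (!chrom %in% names(set)) return(NA_real_)
    w <- Biostrings::width(set[chrom])
    n <- Biostrings::letterFrequency(set[chrom], "N")[1]
    w - n
  }
  a_g <- vapply(chroms, nonN, numeric(1), set = assembly_a)
  b_g <- vapply(chroms, nonN, numeric(1), set = assembly_b)
  lr <- ifelse(!is.na(a_g) & !is.na(b_g) & a_g > 0, b_g / a_g, NA_real_)
  if (anyNA(lr))
    warning("l_r undefined for: ",
            paste(chroms[is.na(lr)], collapse = ", "))
  data.frame(chrom = chroms, a_gapless = a_g, b_gapless = b_g, l_r = lr,
             row.names = NULL, stringsAsFactors = FALSE)
}
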