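SV_TYPES <- c("DEL", "INS", "DUP", "INV")

new_sv_table <- function(df = NULL) {
  base <- data.frame(sv_type = character(), chrom = character(),
                     a_start = numeric(), a_end = numeric(),
                     b_start = numeric(), b_end = numeric(),
                     length = numeric(), continuous = logical(),
                     stringsAsFactors = FALSE)
  if (!is.null(df) && nrow(df)) base <- rbind(base, df[, names(base)])
  class(base) <- c("sv_table", "data.frame")
  base
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Classify intra-chromosomal structural variants
#'
#' Walks the one-to-one synteny chains of name-matched chromosomes and
#' classifies the coordinate gaps between consecutive blocks: an advance
#' on assembly A only is a deletion, an advance on B only an insertion,
#' and an advance on both one deletion plus one insertion (substitution
#' blocks are split into the four counted types). A minus-strand chain
#' flanked by plus-strand synteny on the same chromosome is an inversion
#' over its envelope. Tandem duplications are taken from many-to-one raw
#' alignments in which two disjoint B intervals align to one A interval
#' of the same chromosome; insertion calls explained by a duplicated copy
#' (tandem or an inter-chromosomal segmental duplication) are suppressed
#' so the categories stay disjoint. Every event carries a `continuous`
#' flag, true iff the junction context is N-free on both assemblies.
#'
#' Chains linking differently named chromosomes are skipped with a
#' warning (translocations are out of scope).
#'
#' @param synteny a [one_to_one_map()] result.
#' @param blocks the raw [alignment_blocks()] the map was built from.
#' @param assembly_a,assembly_b the two assemblies.
#' @param min_gap minimum coordinate advance (bp) called as an event;
#'   smaller jitter is ignored (small variants are out of scope).
#' @param dup_min_len minimum copy length (bp) for duplication detection.
#' @return an `sv_table` data frame with columns `sv_type`, `chrom`,
#'   `a_start`, `a_end`, `b_start`, `b_end`, `length`, `continuous`.
#' @export
classify_svs <- function(synteny, blocks, assembly_a, assembly_b,
                         min_gap = 50L, dup_min_len = 1000L) {
  events <- list()
  add <- function(type, chrom, as_, ae, bs, be, len, cont) {
    events[[length(events) + 1L]] <<- data.frame(
      sv_type = type, chrom = chrom, a_start = as_, a_end = ae,
      b_start = bs, b_end = be, length = len, continuous = cont,
      stringsAsFactors = FALSE)
  }
  has_n <- function(assembly, chrom, s, e) {
    if (e <= s) return(FALSE)
    seq <- Biostrings::subseq(assembly[[chrom]], s + 1L, e)
    Biostrings::countPattern("N", seq, fixed = TRUE) > 0L
  }

  off_diag <- sum(synteny$query_name != synteny$target_name)
  if (off_diag > 0L)
    warning(off_diag, " synteny block(s) link differently named ",
            "chromosomes; skipped for intra-chromosomal SV calling")

  ## suppression intervals for insertion calls explained by duplicated
  ## sequence: inter-chromosomal many-to-one copies (segmental
  ## duplications handled by the SD module)
  suppress <- list()
  mto <- find_many_to_one(blocks, min_len = dup_min_len,
                          anchor_side = "query")
  for (i in seq_len(nrow(mto))) {
    p <- mto[i, ]
    for (cp in 1:2)
      suppress[[length(suppress) + 1L]] <- data.frame(
        chrom = p[[paste0("copy", cp, "_chrom")]],
        start = p[[paste0("copy", cp, "_start")]],
        end = p[[paste0("copy", cp, "_end")]])
  }

  ## intra-chromosomal duplications: two blocks of the same chromosome
  ## whose query intervals overlap (>= dup_min_len) while their projected
  ## target intervals are disjoint -- i.e. two B copies of one A interval.
  ## A tandem copy shifts the downstream diagonal by its own length, so
  ## the second copy surfaces as the overlapping head of the next block.
  proj <- function(k, s, e, bl) {
    ds <- s - bl$query_start[k]; de <- e - bl$query_start[k]
    if (bl$strand[k] == "+")
      c(bl$target_start[k] + ds, bl$target_start[k] + de)
    else c(bl$target_end[k] - de, bl$target_end[k] - ds)
  }
  bl <- as.data.frame(blocks)
  bl <- bl[bl$query_name == bl$target_name, , drop = FALSE]
  bl <- bl[order(bl$query_name, bl$query_start), , drop = FALSE]
  seen_anchor <- character(0)
  for (chrom in unique(bl$query_name)) {
    cb <- bl[bl$query_name == chrom, , drop = FALSE]
    n <- nrow(cb)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      qs <- max(cb$query_start[i], cb$query_start[j])
      qe <- min(cb$query_end[i], cb$query_end[j])
      if (qe - qs < dup_min_len) next
      if (cb$strand[i] != cb$strand[j]) next
      ti <- proj(i, qs, qe, cb); tj <- proj(j, qs, qe, cb)
      if (interval_overlap(ti[1], ti[2], tj[1], tj[2]) > min_gap) next
      key <- sprintf("%s:%d-%d", chrom, round(qs), round(qe))
      if (key %in% seen_anchor) next
      seen_anchor <- c(seen_anchor, key)
      ## report the downstream target interval as the extra copy
      tb <- if (tj[1] >= ti[1]) tj else ti
      cont <- !has_n(assembly_a, chrom, qs, qe) &&
        !has_n(assembly_b, chrom, ti[1], ti[2]) &&
        !has_n(assembly_b, chrom, tj[1], tj[2])
      add("DUP", chrom, qs, qe, tb[1], tb[2], qe - qs, cont)
      suppress[[length(suppress) + 1L]] <-
        data.frame(chrom = chrom, start = ti[1], end = ti[2])
      suppress[[length(suppress) + 1L]] <-
        data.frame(chrom = chrom, start = tj[1], end = tj[2])
    }
  }
  suppress <- if (length(suppress)) do.call(rbind, suppress) else
    data.frame(chrom = character(), start = numeric(), end = numeric())

  same <- synteny[synteny$query_name == synteny$target_name, , drop = FALSE]

  ## inversions: minus-strand chains with plus-strand context on the
  ## same chromosome
  inv_envs <- data.frame(chrom = character(), a_start = numeric(),
                         a_end = numeric())
  for (cid in unique(same$chain_id)) {
    ch <- same[same$chain_id == cid, , drop = FALSE]
    if (ch$strand[1] != "-") next
    chrom <- ch$query_name[1]
    a0 <- min(ch$query_start); a1 <- max(ch$query_end)
    b0 <- min(ch$target_start); b1 <- max(ch$target_end)
    plus <- same[same$query_name == chrom & same$strand == "+", ,
                 drop = FALSE]
    if (!any(plus$query_end <= a0 + min_gap) ||
        !any(plus$query_start >= a1 - min_gap)) next
    len <- max(a1 - a0, b1 - b0)
    cont <- !has_n(assembly_a, chrom, a0, a1) &&
      !has_n(assembly_b, chrom, b0, b1)
    add("INV", chrom, a0, a1, b0, b1, len, cont)
    inv_envs <- rbind(inv_envs,
                      data.frame(chrom = chrom, a_start = a0, a_end = a1))
  }

  in_suppressed <- function(chrom, s, e) {
    if (e <= s || nrow(suppress) == 0L) return(FALSE)
    hit <- suppress$chrom == chrom &
      interval_overlap(suppress$start, suppress$end, s, e) >= 0.5 * (e - s)
    any(hit)
  }
  in_inversion <- function(chrom, s, e) {
    if (e <= s || nrow(inv_envs) == 0L) return(FALSE)
    hit <- inv_envs$chrom == chrom &
      interval_overlap(inv_envs$a_start, inv_envs$a_end, s, e) >=
        0.5 * (e - s)
    any(hit)
  }

  ## deletions and insertions from within-chain junctions
  for (cid in unique(same$chain_id)) {
    ch <- same[same$chain_id == cid, , drop = FALSE]
    if (nrow(ch) < 2L) next
    ch <- ch[order(ch$query_start), , drop = FALSE]
    chrom <- ch$query_name[1]
    minus <- ch$strand[1] == "-"
    for (i in seq_len(nrow(ch) - 1L)) {
      dq <- ch$query_start[i + 1L] - ch$query_end[i]
      if (minus) {
        bs <- ch$target_end[i + 1L]; be <- ch$target_start[i]
      } else {
        bs <- ch$target_end[i]; be <- ch$target_start[i + 1L]
      }
      dt <- be - bs
      if (dq < min_gap && dt < min_gap) next
      a0 <- ch$query_end[i]; a1 <- ch$query_start[i + 1L]
      cont <- !has_n(assembly_a, chrom, a0, max(a1, a0)) &&
        !has_n(assembly_b, chrom, bs, max(be, bs))
      if (dq >= min_gap && dt >= min_gap &&
          in_inversion(chrom, a0, a1)) next
      if (dq >= min_gap)
        add("DEL", chrom, a0, a1, bs, bs, dq, cont)
      if (dt >= min_gap && !in_suppressed(chrom, bs, be))
        add("INS", chrom, a0, a0, bs, be, dt, cont)
    }
  }

  out <- if (length(events)) do.call(rbind, events) else NULL
  new_sv_table(out)
}

#' Filter structural variants by length and continuity
#'
#' Keeps events of at least `min_len` bp (so a 1 kb event survives the
#' "shorter than 1 kb" removal) and, when `require_continuous`, only
#' events whose junction context is free of N on both assemblies.
#'
#' @param svs an `sv_table`.
#' @param min_len minimum event length in bp.
#' @param require_continuous drop events overlapping assembly gaps?
#' @return the filtered `sv_table`.
#' @export
filter_svs <- function(svs, min_len = 1000L, require_continuous = TRUE) {
  keep <- svs$length >= min_len
  if (require_continuous) keep <- keep & svs$continuous
  new_sv_table(svs[keep, , drop = FALSE])
}

#' Chromosome metadata table
#'
#' @param assembly a named [Biostrings::DNAStringSet].
#' @param x_name name of the X chromosome or `NA`.
#' @return data frame `chrom`, `length`, `is_x`.
#' @export
chrom_table <- function(assembly, x_name = NA_character_) {
  data.frame(chrom = names(assembly),
             length = as.numeric(Biostrings::width(assembly)),
             is_x = !is.na(x_name) & names(assembly) == x_name,
             stringsAsFactors = FALSE)
}

#' Count events per chromosome and category
#'
#' @param svs an `sv_table` (column `sv_type`) or any data frame with a
#'   `chrom` column and a category column named by `category_col`.
#' @param chroms a [chrom_table()] data frame.
#' @param category_col name of the category column.
#' @return the chromosome table with one count column per category,
#'   class `chrom_count_table`.
#' @export
count_by_chromosome <- function(svs, chroms, category_col = "sv_type") {
  unknown <- setdiff(unique(svs$chrom), chroms$chrom)
  if (length(unknown))
    stop("events on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  cats <- if (category_col == "sv_type") SV_TYPES else
    sort(unique(svs[[category_col]]))
  out <- chroms
  for (cat in cats) {
    sub <- svs[svs[[category_col]] == cat, , drop = FALSE]
    out[[cat]] <- as.integer(table(factor(sub$chrom,
                                          levels = chroms$chrom)))
  }
  class(out) <- c("chrom_count_table", "data.frame")
  out
}

#' Match called structural variants against a truth table
#'
#' A truth event matches a call of the same type on the same chromosome
#' when their assembly-A intervals overlap reciprocally by at least
#' `min_recip` (deletions, duplications, inversions) or, for insertions,
#' when the insertion points are within `max_shift` bp and the lengths
#' agree within `len_tol` (relative). Matching is one-to-one and greedy.
#'
#' @param calls an `sv_table` of called events.
#' @param truth a truth table from [simulate_pair()] (rows `role == "sv"`).
#' @param min_recip minimum reciprocal overlap.
#' @param max_shift maximum insertion-point shift (bp).
#' @param len_tol relative length tolerance for insertions.
#' @return list with `precision`, `recall`, `n_calls`, `n_truth`,
#'   `matched` (logical per truth row).
#' @export
evaluate_sv_calls <- function(calls, truth, min_recip = 0.5,
                              max_shift = 200L, len_tol = 0.2) {
  tr <- truth[truth$role == "sv", , drop = FALSE]
  used <- rep(FALSE, nrow(calls))
  matched <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    for (j in seq_len(nrow(calls))) {
      if (used[j]) next
      c <- calls[j, ]
      if (c$sv_type != t$kind || c$chrom != t$chrom) next
      ok <- if (t$kind == "INS") {
        abs(c$a_start - t$start) <= max_shift &&
          abs(c$length - t$length) <= len_tol * t$length
      } else {
        ov <- interval_overlap(c$a_start, c$a_end, t$start, t$end)
        ov >= min_recip * (c$a_end - c$a_start) &&
          ov >= min_recip * (t$end - t$start)
      }
      if (ok) { used[j] <- TRUE; matched[i] <- TRUE; break }
    }
  }
  list(precision = if (nrow(calls)) sum(used) / nrow(calls) else NA_real_,
       recall = if (nrow(tr)) sum(matched) / nrow(tr) else NA_real_,
       n_calls = nrow(calls), n_truth = nrow(tr), matched = matched,
       call_matched = used)
}

#' Write structural variants as TSV or VCF
#'
#' The TSV is BED-like (0-based half-open assembly-A coordinates); the
#' VCF uses 1-based positions and symbolic ALT alleles (`<DEL>`, `<INS>`,
#' `<DUP>`, `<INV>`) with `SVTYPE`, `END` and `SVLEN` INFO fields.
#'
#' @param svs an `sv_table`.
#' @param path output path.
#' @param assembly_a assembly A (for VCF REF bases and contig headers).
#' @return `path`, invisibly.
#' @export
write_sv_tsv <- function(svs, path) {
  write.table(as.data.frame(svs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv_tsv
#' @export
read_sv_tsv <- function(path) {
  new_sv_table(read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE))
}

#' @rdname write_sv_tsv
#' @export
write_sv_vcf <- function(svs, assembly_a, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=asmpair",
           sprintf("##contig=<ID=%s,length=%d>", names(assembly_a),
                   Biostrings::width(assembly_a)),
           '##ALT=<ID=DEL,Description="Deletion">',
           '##ALT=<ID=INS,Description="Insertion">',
           '##ALT=<ID=DUP,Description="Duplication">',
           '##ALT=<ID=INV,Description="Inversion">',
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(svs)) {
    pos <- pmax(1, svs$a_start)  # 1-based position of the base at/before
    ref <- vapply(seq_len(nrow(svs)), function(i)
      as.character(Biostrings::subseq(assembly_a[[svs$chrom[i]]],
                                      pos[i], pos[i])), character(1))
    svlen <- ifelse(svs$sv_type == "DEL", -svs$length, svs$length)
    rows <- sprintf("%s\t%d\t%s\t%s\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d",
                    svs$chrom, as.integer(pos),
                    sprintf("sv%03d", seq_len(nrow(svs))), ref,
                    svs$sv_type, svs$sv_type,
                    as.integer(pmax(svs$a_end, pos)), as.integer(svlen))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
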