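#' Detect many-to-one alignments (segmental duplication candidates)
#'
#' Groups raw alignment blocks that share one locus on the anchor side of
#' the alignment while their loci on the other side (the copies) are
#' distinct: the signature of a segmental duplication. Blocks qualify when
#' both aligned spans are at least `min_len` and their anchor-side overlap
#' is at least `min_reciprocal_overlap` of the shorter block. Families
#' with three or more copies emit all pairwise combinations sharing a
#' `family_id`.
#'
#' With the default `anchor_side = "query"` the anchor locus lies in the
#' query assembly (A) and the copies in the target assembly (B), matching
#' a comparison in which the derived copy was inserted into B; pass
#' `anchor_side = "target"` to swap the roles.
#'
#' @param blocks raw (pre-one-to-one) [alignment_blocks()].
#' @param min_len minimum aligned span (bp) of each block.
#' @param min_reciprocal_overlap anchor-side overlap fraction required to
#'   treat two blocks as aligning to the same locus.
#' @param anchor_side `"query"` or `"target"`.
#' @return data frame of SD pairs (`family_id`, anchor locus, two copy
#'   loci with block identities, `length`), class `sd_pairs`, with
#'   attribute `copy_side`.
#' @export
find_many_to_one <- function(blocks, min_len = 1000L,
                             min_reciprocal_overlap = 0.8,
                             anchor_side = c("query", "target")) {
  anchor_side <- match.arg(anchor_side)
  copy_side <- if (anchor_side == "query") "target" else "query"
  a_ch <- blocks[[paste0(anchor_side, "_name")]]
  a_s <- blocks[[paste0(anchor_side, "_start")]]
  a_e <- blocks[[paste0(anchor_side, "_end")]]
  c_ch <- blocks[[paste0(copy_side, "_name")]]
  span_ok <- (blocks$query_end - blocks$query_start) >= min_len &
    (blocks$target_end - blocks$target_start) >= min_len
  idx <- which(span_ok)

  ## project an anchor-side interval through block i onto the copy side
  project <- function(i, s, e) {
    ds <- s - a_s[i]; de <- e - a_s[i]
    if (anchor_side == "query") {
      if (blocks$strand[i] == "+")
        c(blocks$target_start[i] + ds, blocks$target_start[i] + de)
      else
        c(blocks$target_end[i] - de, blocks$target_end[i] - ds)
    } else {
      if (blocks$strand[i] == "+")
        c(blocks$query_start[i] + ds, blocks$query_start[i] + de)
      else
        c(blocks$query_end[i] - de, blocks$query_end[i] - ds)
    }
  }

  pairs <- list()
  parent_of <- seq_along(a_ch)  # union-find for family ids
  find_root <- function(i) { while (parent_of[i] != i) i <- parent_of[i]; i }
  for (u in seq_along(idx)) {
    i <- idx[u]
    for (v in seq_len(u - 1L)) {
      j <- idx[v]
      if (a_ch[i] != a_ch[j]) next
      as_ <- max(a_s[i], a_s[j]); ae <- min(a_e[i], a_e[j])
      ov <- ae - as_
      shorter <- min(a_e[i] - a_s[i], a_e[j] - a_s[j])
      if (ov < min_len || ov < min_reciprocal_overlap * shorter) next
      ci <- project(i, as_, ae); cj <- project(j, as_, ae)
      ## copies must come from different loci
      if (c_ch[i] == c_ch[j] &&
          interval_overlap(ci[1], ci[2], cj[1], cj[2]) > 0) next
      parent_of[find_root(i)] <- find_root(j)
      ## canonical copy order: (chrom, start)
      first <- if (c_ch[i] < c_ch[j] ||
                   (c_ch[i] == c_ch[j] && ci[1] <= cj[1])) i else j
      second <- if (first == i) j else i
      cf <- if (first == i) ci else cj
      cs2 <- if (first == i) cj else ci
      pairs[[length(pairs) + 1L]] <- data.frame(
        block1 = first, block2 = second,
        anchor_chrom = a_ch[i],
        anchor_start = as_, anchor_end = ae,
        copy1_chrom = c_ch[first], copy1_start = cf[1], copy1_end = cf[2],
        copy2_chrom = c_ch[second], copy2_start = cs2[1],
        copy2_end = cs2[2],
        copy1_block_identity = blocks$identity[first],
        copy2_block_identity = blocks$identity[second],
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0L) {
    out <- data.frame(family_id = integer(), anchor_chrom = character(),
                      anchor_start = numeric(), anchor_end = numeric(),
                      copy1_chrom = character(), copy1_start = numeric(),
                      copy1_end = numeric(), copy2_chrom = character(),
                      copy2_start = numeric(), copy2_end = numeric(),
                      copy1_block_identity = numeric(),
                      copy2_block_identity = numeric(),
                      length = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, pairs)
    roots <- vapply(out$block1, find_root, integer(1))
    out$family_id <- as.integer(factor(roots, levels = unique(roots)))
    out$length <- out$anchor_end - out$anchor_start
    out <- out[, c("family_id", setdiff(names(out),
                                        c("family_id", "block1", "block2")))]
  }
  attr(out, "copy_side") <- copy_side
  class(out) <- c("sd_pairs", "data.frame")
  out
}

copy_side_of <- function(pairs) {
  cs <- attr(pairs, "copy_side")
  if (is.null(cs)) "target" else cs
}

#' Classify SD pairs as boundary-derived or internal-derived
#'
#' A copy's enclosing synteny chain is the chain whose blocks overlap the
#' copy locus most (on the copy-side assembly). A pair is boundary-derived
#' (`bSD`) when either copy has no enclosing chain, extends beyond its
#' chain's envelope, or lies within `boundary_tol` of the envelope's end;
#' otherwise it is internal-derived (`iSD`). Each copy's `chain_span` is
#' recorded for the parental-resolution rule.
#'
#' @param pairs an `sd_pairs` data frame.
#' @param synteny a [one_to_one_map()] result.
#' @param boundary_tol distance (bp) from a chain end that still counts
#'   as the boundary.
#' @return `pairs` with `sd_class`, `chain_span1`, `chain_span2` columns.
#' @export
classify_sd <- function(pairs, synteny, boundary_tol = 1000L) {
  cs <- copy_side_of(pairs)
  s_ch <- synteny[[paste0(cs, "_name")]]
  s_s <- synteny[[paste0(cs, "_start")]]
  s_e <- synteny[[paste0(cs, "_end")]]
  copy_status <- function(chrom, cstart, cend) {
    hit <- which(s_ch == chrom &
                   interval_overlap(s_s, s_e, cstart, cend) > 0)
    if (length(hit) == 0L)
      return(list(bsd = TRUE, span = 0))
    ov <- interval_overlap(s_s[hit], s_e[hit], cstart, cend)
    per_chain <- tapply(ov, synteny$chain_id[hit], sum)
    ## a copy is enclosed only if chain blocks actually cover it; a few
    ## jittered base pairs of contact with flanking blocks do not count
    if (max(per_chain) < 0.5 * (cend - cstart))
      return(list(bsd = TRUE, span = 0))
    best_chain <- as.integer(names(per_chain)[which.max(per_chain)])
    in_chain <- which(synteny$chain_id == best_chain & s_ch == chrom)
    env0 <- min(s_s[in_chain]); env1 <- max(s_e[in_chain])
    bsd <- cstart < env0 + boundary_tol || cend > env1 - boundary_tol
    list(bsd = bsd, span = synteny$chain_span[in_chain[1]])
  }
  n <- nrow(pairs)
  pairs$sd_class <- character(n)
  pairs$chain_span1 <- numeric(n)
  pairs$chain_span2 <- numeric(n)
  for (i in seq_len(n)) {
    st1 <- copy_status(pairs$copy1_chrom[i], pairs$copy1_start[i],
                       pairs$copy1_end[i])
    st2 <- copy_status(pairs$copy2_chrom[i], pairs$copy2_start[i],
                       pairs$copy2_end[i])
    pairs$sd_class[i] <- if (st1$bsd || st2$bsd) "bSD" else "iSD"
    pairs$chain_span1[i] <- st1$span
    pairs$chain_span2[i] <- st2$span
  }
  pairs
}

#' Resolve the parental copy and duplication direction of SD pairs
#'
#' Internal-derived pairs (`iSD`) use the synteny-length rule: the copy
#' whose enclosing chain spans more base pairs is parental. Boundary-
#' derived pairs (`bSD`) use the identity rule: each copy is aligned
#' against the anchor locus of the other assembly and the copy with the
#' higher nucleotide identity is parental, provided that identity exceeds
#' `min_identity`; ties (and iSD chain-span ties falling back to the
#' identity rule) resolve to `unresolved`. The direction category follows
#' from the parental copy's chromosome class (X or autosome) and the
#' derived copy's chromosome class.
#'
#' @param pairs classified `sd_pairs` (after [classify_sd()]).
#' @param assembly_copy assembly holding the copies (B for the default
#'   orientation).
#' @param assembly_anchor assembly holding the anchor loci (A).
#' @param x_name name of the X chromosome, or `NA`.
#' @param min_identity identity that the winning bSD copy must exceed.
#' @return `pairs` with `copy1_identity`, `copy2_identity`, `parental`
#'   (`copy1`/`copy2`/`unresolved`), `parent_chrom`, `derived_chrom` and
#'   `direction` (`A>A`, `A>X`, `X>A`, `X>X` or `unresolved`).
#' @export
resolve_parent <- function(pairs, assembly_copy, assembly_anchor,
                           x_name = NA_character_, min_identity = 0.90) {
  n <- nrow(pairs)
  pairs$copy1_identity <- NA_real_
  pairs$copy2_identity <- NA_real_
  pairs$parental <- rep("unresolved", n)
  pairs$parent_chrom <- NA_character_
  pairs$derived_chrom <- NA_character_
  pairs$direction <- rep("unresolved", n)
  cls <- function(ch) ifelse(!is.na(x_name) & ch == x_name, "X", "A")
  copy_seq <- function(chrom, s, e) {
    if (!chrom %in% names(assembly_copy)) return(NULL)
    Biostrings::subseq(assembly_copy[[chrom]], s + 1L, e)
  }
  for (i in seq_len(n)) {
    p <- pairs[i, ]
    identity_rule <- function() {
      anc <- if (p$anchor_chrom %in% names(assembly_anchor))
        Biostrings::subseq(assembly_anchor[[p$anchor_chrom]],
                           p$anchor_start + 1L, p$anchor_end) else NULL
      s1 <- copy_seq(p$copy1_chrom, p$copy1_start, p$copy1_end)
      s2 <- copy_seq(p$copy2_chrom, p$copy2_start, p$copy2_end)
      if (is.null(anc) || is.null(s1) || is.null(s2)) {
        warning("missing sequence for SD pair ", i,
                "; parental left unresolved")
        return(NULL)
      }
      id1 <- pairwise_identity(s1, anc)
      id2 <- pairwise_identity(s2, anc)
      pairs$copy1_identity[i] <<- id1
      pairs$copy2_identity[i] <<- id2
      if (id1 == id2) return(NULL)
      win <- if (id1 > id2) 1L else 2L
      if (max(id1, id2) <= min_identity) return(NULL)
      win
    }
    win <- if (p$sd_class == "iSD" && p$chain_span1 != p$chain_span2) {
      if (p$chain_span1 > p$chain_span2) 1L else 2L
    } else identity_rule()
    if (is.null(win)) next
    parent_ch <- pairs[[paste0("copy", win, "_chrom")]][i]
    derived_ch <- pairs[[paste0("copy", 3L - win, "_chrom")]][i]
    pairs$parental[i] <- paste0("copy", win)
    pairs$parent_chrom[i] <- parent_ch
    pairs$derived_chrom[i] <- derived_ch
    pairs$direction[i] <- paste0(cls(parent_ch), ">", cls(derived_ch))
  }
  pairs
}

#' Tally SD directions per chromosome
#'
#' Each resolved pair increments exactly one direction category on the
#' chromosome of its derived copy; unresolved pairs are tallied
#' separately, so categories conserve the total pair count.
#'
#' @param pairs resolved `sd_pairs` (after [resolve_parent()]).
#' @param chroms a [chrom_table()] data frame.
#' @return list with `counts` (a `chrom_count_table` with one column per
#'   direction), `unresolved` and `total`.
#' @export
categorize_direction <- function(pairs, chroms) {
  resolved <- pairs[pairs$direction != "unresolved", , drop = FALSE]
  df <- data.frame(chrom = resolved$derived_chrom,
                   direction = factor(resolved$direction,
                                      levels = c("A>A", "A>X", "X>A", "X>X")),
                   stringsAsFactors = FALSE)
  out <- chroms
  for (cat in levels(df$direction))
    out[[cat]] <- as.integer(table(factor(
      df$chrom[df$direction == cat], levels = chroms$chrom)))
  class(out) <- c("chrom_count_table", "data.frame")
  list(counts = out, unresolved = nrow(pairs) - nrow(resolved),
       total = nrow(pairs))
}

#' Genes intersecting derived SD copies
#'
#' Lists, for each resolved SD pair, the gene identifiers whose span
#' intersects the derived copy interval by at least one base pair. The
#' annotation must be in the coordinates of the assembly holding the
#' copies. Genes on chromosomes absent from `known_chroms` (when given)
#' are skipped with a warning.
#'
#' @param pairs resolved `sd_pairs`.
#' @param genes data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, e.g. from [read_gene_annotation()].
#' @param known_chroms optional character vector of valid chromosomes.
#' @return list of sorted, deduplicated gene-id vectors, one per pair
#'   (empty for unresolved pairs), with the union in attribute `all_genes`.
#' @export
genes_in_derived <- function(pairs, genes, known_chroms = NULL) {
  if (!is.null(known_chroms)) {
    bad <- !genes$chrom %in% known_chroms
    if (any(bad)) {
      warning("skipping ", sum(bad),
              " gene(s) on unknown chromosome(s): ",
              paste(unique(genes$chrom[bad]), collapse = ", "))
      genes <- genes[!bad, , drop = FALSE]
    }
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$parental[i] == "unresolved") { out[[i]] <- character(0); next }
    dwin <- if (pairs$parental[i] == "copy1") 2L else 1L
    ch <- pairs[[paste0("copy", dwin, "_chrom")]][i]
    s <- pairs[[paste0("copy", dwin, "_start")]][i]
    e <- pairs[[paste0("copy", dwin, "_end")]][i]
    hit <- genes$chrom == ch &
      interval_overlap(genes$start, genes$end, s, e) >= 1
    out[[i]] <- sort(unique(genes$gene_id[hit]))
  }
  attr(out, "all_genes") <- sort(unique(unlist(out)))
  out
}

#' Read a gene annotation as a 0-based interval table
#'
#' Imports GFF3 or BED via rtracklayer and converts to the package's
#' 0-based half-open convention, keeping `gene`-type records for GFF3.
#'
#' @param path GFF3 or BED file.
#' @return data frame `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_annotation requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
    else if ("Name" %in% names(mc)) as.character(mc$Name)
    else if ("name" %in% names(mc)) as.character(mc$name)
    else paste0("gene", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene_id = id, stringsAsFactors = FALSE)
}

#' Compare called SD pairs and directions against a truth table
#'
#' Truth events are matched to called pairs through the anchor locus
#' (assembly-A coordinates, which the parental truth row uses), requiring
#' reciprocal overlap of at least `min_recip`. A matched, resolved pair is
#' correct when its parental copy lies on the truth parent chromosome and
#' its derived copy on the truth derived chromosome.
#'
#' @param pairs resolved `sd_pairs`.
#' @param truth truth table from [simulate_pair()].
#' @param min_recip minimum reciprocal anchor overlap.
#' @return list with `n_truth`, `n_matched`, `n_resolved`, `n_correct`,
#'   `direction_accuracy` (correct / resolved-and-matched) and `recall`.
#' @export
evaluate_sd_directions <- function(pairs, truth, min_recip = 0.5) {
  par_rows <- truth[truth$kind == "SD" & truth$role == "parent", ,
                    drop = FALSE]
  der_rows <- truth[truth$kind == "SD" & truth$role == "derived", ,
                    drop = FALSE]
  n_matched <- 0L; n_resolved <- 0L; n_correct <- 0L
  for (i in seq_len(nrow(par_rows))) {
    t <- par_rows[i, ]
    d <- der_rows[der_rows$event_id == t$event_id, ]
    hit <- which(pairs$anchor_chrom == t$chrom &
                   interval_overlap(pairs$anchor_start, pairs$anchor_end,
                                    t$start, t$end) >=
                   min_recip * pmax(pairs$anchor_end - pairs$anchor_start,
                                    t$end - t$start))
    if (length(hit) == 0L) next
    n_matched <- n_matched + 1L
    j <- hit[1]
    if (pairs$parental[j] == "unresolved") next
    n_resolved <- n_resolved + 1L
    if (identical(pairs$parent_chrom[j], t$chrom) &&
        identical(pairs$derived_chrom[j], d$chrom[1]))
      n_correct <- n_correct + 1L
  }
  list(n_truth = nrow(par_rows), n_matched = n_matched,
       n_resolved = n_resolved, n_correct = n_correct,
       direction_accuracy = if (n_resolved > 0)
         n_correct / n_resolved else NA_real_,
       recall = if (nrow(par_rows) > 0)
         n_matched / nrow(par_rows) else NA_real_)
}
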