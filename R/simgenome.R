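#' Configuration for a simulated assembly pair
#'
#' Builds and validates the configuration used by [simulate_pair()]. The
#' simulator derives assembly B from a shared ancestral sequence by applying
#' background substitutions and planted events, while assembly A receives
#' N-gap runs only (the "reference-like" genome). Defaults plant structural
#' variants at 10 events/Mb split over the four types and 12 segmental
#' duplications split evenly over the three direction categories.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param x_name name of the X chromosome, or `NA` for an all-autosome
#'   genome (then no X-involving SD categories may be requested).
#' @param background_divergence substitution rate per bp applied to
#'   assembly B everywhere.
#' @param sv_rates named vector of events per Mb for `DEL`, `INS`, `DUP`,
#'   `INV`; counts are `round(rate * total Mb)`.
#' @param sv_length_range length range (bp) for planted SVs.
#' @param sd_counts named vector of planted segmental duplications per
#'   direction category (`A>A`, `A>X`, `X>A`).
#' @param sd_length_range length range (bp, both ends >= 1000) for SDs.
#' @param derived_extra_divergence substitution rate applied only to the
#'   derived SD copy; must exceed `background_divergence`.
#' @param ngap_count number of N-gap runs planted in assembly A.
#' @param ngap_length_range length range (bp) of the N-gap runs.
#' @param margin minimum spacing (bp) between planted events and from
#'   chromosome ends, so every event retains alignable flanks.
#' @param planted_events optional data frame of prescribed events with
#'   columns `kind`, `chrom`, `start`, `length` (0-based start; `start`
#'   may be `NA` to place randomly). Placed before rate-based events.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_lengths,
                       x_name = NA_character_,
                       background_divergence = 0.001,
                       sv_rates = c(DEL = 3, INS = 3, DUP = 2, INV = 2),
                       sv_length_range = c(200L, 50000L),
                       sd_counts = c("A>A" = 4L, "A>X" = 4L, "X>A" = 4L),
                       sd_length_range = c(2000L, 10000L),
                       derived_extra_divergence = 0.02,
                       ngap_count = 5L,
                       ngap_length_range = c(500L, 3000L),
                       margin = 2500L,
                       planted_events = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names")
  if (!is.na(x_name) && !x_name %in% names(chrom_lengths))
    stop("x_name not among chromosome names")
  sv_rates <- sv_rates[c("DEL", "INS", "DUP", "INV")]
  sv_rates[is.na(sv_rates)] <- 0
  names(sv_rates) <- c("DEL", "INS", "DUP", "INV")
  sd_counts <- sd_counts[c("A>A", "A>X", "X>A")]
  sd_counts[is.na(sd_counts)] <- 0L
  names(sd_counts) <- c("A>A", "A>X", "X>A")
  rng_ok <- function(r) length(r) == 2L && r[1] > 0 && r[2] >= r[1]
  stopifnot(rng_ok(sv_length_range), rng_ok(sd_length_range),
            rng_ok(ngap_length_range))
  if (sum(sd_counts) > 0 && sd_length_range[1] < 1000)
    stop("sd_length_range must be >= 1000 bp")
  if (background_divergence < 0 || derived_extra_divergence < 0)
    stop("divergences must be >= 0")
  if (sum(sd_counts) > 0 &&
      background_divergence >= derived_extra_divergence)
    stop("background_divergence must be < derived_extra_divergence")
  autosomes <- setdiff(names(chrom_lengths), x_name)
  if ((sd_counts["A>X"] > 0 || sd_counts["X>A"] > 0) && is.na(x_name))
    stop("X-involving SD categories require x_name")
  if (sd_counts["A>A"] > 0 && length(autosomes) < 2)
    stop("A>A duplications require at least two autosomes")
  structure(list(
    seed = as.integer(seed),
    chrom_lengths = as.integer(round(chrom_lengths)) |>
      stats::setNames(names(chrom_lengths)),
    x_name = x_name,
    background_divergence = background_divergence,
    sv_rates = sv_rates,
    sv_length_range = as.integer(sv_length_range),
    sd_counts = as.integer(sd_counts) |> stats::setNames(names(sd_counts)),
    sd_length_range = as.integer(sd_length_range),
    derived_extra_divergence = derived_extra_divergence,
    ngap_count = as.integer(ngap_count),
    ngap_length_range = as.integer(ngap_length_range),
    margin = as.integer(margin),
    planted_events = planted_events
  ), class = "sim_config")
}

RAW_BASES <- charToRaw("ACGT")

random_dna_raw <- function(n) RAW_BASES[sample.int(4L, n, replace = TRUE)]

revcomp_raw <- function(x) {
  lut <- raw(256)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- charToRaw("TGCA")
  lut[as.integer(charToRaw("N")) + 1L] <- charToRaw("N")
  rev(lut[as.integer(x) + 1L])
}

# substitute bases at rate p; returns the raw vector
mutate_raw <- function(x, p) {
  if (p <= 0) return(x)
  n <- length(x)
  nmut <- rbinom(1L, n, p)
  if (nmut == 0L) return(x)
  idx <- sample.int(n, nmut)
  code <- match(x[idx], RAW_BASES)                # 1..4
  shift <- sample.int(3L, nmut, replace = TRUE)   # 1..3, never identity
  x[idx] <- RAW_BASES[((code - 1L + shift) %% 4L) + 1L]
  x
}

empty_truth <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             event_id = character(), kind = character(),
             direction = character(), role = character(),
             length = integer(), boundary_flag = logical(),
             stringsAsFactors = FALSE)
}

# rejection-sample an interval of `len` on one of `chroms`, at least
# `margin` from ends and from every reserved interval
place_interval <- function(occupied, chrom_lengths, chroms, len, margin,
                           max_try = 200L) {
  w <- chrom_lengths[chroms]
  feasible <- chroms[w >= len + 2L * margin]
  if (length(feasible) == 0L) return(NULL)
  wf <- as.numeric(chrom_lengths[feasible])
  for (i in seq_len(max_try)) {
    chrom <- if (length(feasible) == 1L) feasible else
      sample(feasible, 1L, prob = wf)
    L <- chrom_lengths[[chrom]]
    start <- sample.int(L - len - 2L * margin + 1L, 1L) + margin - 1L
    cand <- IRanges::IRanges(start + 1L - margin, start + len + margin)
    occ <- occupied[[chrom]]
    if (is.null(occ) ||
        length(IRanges::findOverlaps(cand, occ)) == 0L)
      return(list(chrom = chrom, start = start, end = start + len))
  }
  NULL
}

#' Simulate a related assembly pair with planted events
#'
#' Generates an ancestral genome, derives assembly B from it by applying
#' background substitutions and the planted events (deletions, insertions,
#' tandem duplications, inversions and inserted derived segmental
#' duplication copies), and derives assembly A by overwriting planted N-gap
#' runs. Planted events are rejection-sampled to be mutually disjoint with
#' a safety margin; identical configurations give byte-identical output.
#'
#' Coordinates in the truth table are 0-based half-open. Structural
#' variants are recorded at their assembly-A locus (insertions as a
#' zero-width interval at the insertion point); segmental duplications
#' produce two truth rows sharing an `event_id`: the parental locus in
#' assembly-A coordinates (`role = "parent"`) and the inserted copy in
#' assembly-B coordinates (`role = "derived"`).
#'
#' @param config a [sim_config()] object.
#' @return a list of class `assembly_pair` with elements `a` and `b`
#'   ([Biostrings::DNAStringSet]), `truth` (data frame), `x_name`
#'   and `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$chrom_lengths
  chroms <- names(cl)
  autosomes <- setdiff(chroms, config$x_name)

  set.seed(config$seed)
  substream <- sample.int(.Machine$integer.max - 1L, 8L)
  names(substream) <- c("genome", "ngap", "sv", "sd", "background",
                        "insseq", "derived", "spare")

  ## ancestral sequence (also the gapless backbone of assembly A)
  set.seed(substream[["genome"]])
  anc <- lapply(cl, random_dna_raw)

  occupied <- stats::setNames(vector("list", length(chroms)), chroms)
  reserve <- function(chrom, start, end) {
    r <- IRanges::IRanges(start + 1L, max(end, start + 1L))
    occupied[[chrom]] <<- if (is.null(occupied[[chrom]])) r else
      c(occupied[[chrom]], r)
  }

  ## N-gap runs, assembly A only
  set.seed(substream[["ngap"]])
  ngaps <- list()
  for (i in seq_len(config$ngap_count)) {
    len <- sample(config$ngap_length_range[1]:config$ngap_length_range[2], 1L)
    p <- place_interval(occupied, cl, chroms, len, config$margin)
    if (is.null(p)) stop("genome too small for requested events (N-gaps)")
    reserve(p$chrom, p$start, p$end)
    ngaps[[i]] <- p
  }

  ## planted SVs: explicit events first, then rate-based counts
  events <- list()
  add_event <- function(kind, chrom, start, end, len) {
    events[[length(events) + 1L]] <<- list(kind = kind, chrom = chrom,
                                           start = start, end = end,
                                           len = len)
  }
  set.seed(substream[["sv"]])
  if (!is.null(config$planted_events)) {
    pe <- config$planted_events
    for (i in seq_len(nrow(pe))) {
      len <- as.integer(pe$length[i])
      if (!is.na(pe$start[i])) {
        s <- as.integer(pe$start[i])
        e <- if (pe$kind[i] == "INS") s else s + len
        reserve(pe$chrom[i], s, e)
        add_event(pe$kind[i], pe$chrom[i], s, e, len)
      } else {
        p <- place_interval(occupied, cl, pe$chrom[i], len, config$margin)
        if (is.null(p)) stop("genome too small for requested events")
        reserve(p$chrom, p$start, p$end)
        add_event(pe$kind[i], p$chrom, p$start,
                  if (pe$kind[i] == "INS") p$start else p$end, len)
      }
    }
  }
  total_mb <- sum(as.numeric(cl)) / 1e6
  for (kind in c("DEL", "INS", "DUP", "INV")) {
    n <- round(config$sv_rates[[kind]] * total_mb)
    for (i in seq_len(n)) {
      len <- sample(config$sv_length_range[1]:config$sv_length_range[2], 1L)
      p <- place_interval(occupied, cl, chroms, len, config$margin)
      if (is.null(p)) stop("genome too small for requested events")
      reserve(p$chrom, p$start, p$end)
      add_event(kind, p$chrom, p$start,
                if (kind == "INS") p$start else p$end, len)
    }
  }

  ## segmental duplications: parent interval plus insertion point
  set.seed(substream[["sd"]])
  sds <- list()
  for (cat in c("A>A", "A>X", "X>A")) {
    for (i in seq_len(config$sd_counts[[cat]])) {
      len <- sample(config$sd_length_range[1]:config$sd_length_range[2], 1L)
      parent_pool <- switch(cat, "X>A" = config$x_name, autosomes)
      p <- place_interval(occupied, cl, parent_pool, len, config$margin)
      if (is.null(p)) stop("genome too small for requested events (SD parent)")
      reserve(p$chrom, p$start, p$end)
      target_pool <- switch(cat,
                            "A>X" = config$x_name,
                            setdiff(autosomes, p$chrom))
      if (cat == "X>A") target_pool <- autosomes
      q <- place_interval(occupied, cl, target_pool, 1L, config$margin)
      if (is.null(q)) stop("genome too small for requested events (SD target)")
      reserve(q$chrom, q$start, q$start + 1L)
      sds[[length(sds) + 1L]] <- list(direction = cat, len = len,
                                      parent_chrom = p$chrom,
                                      parent_start = p$start,
                                      target_chrom = q$chrom,
                                      target_pos = q$start)
    }
  }

  ## background substitutions for assembly B
  set.seed(substream[["background"]])
  bseq <- lapply(anc, mutate_raw, p = config$background_divergence)

  ## novel insertion sequences and derived SD copies
  set.seed(substream[["insseq"]])
  for (i in seq_along(events))
    if (events[[i]]$kind == "INS")
      events[[i]]$insseq <- random_dna_raw(events[[i]]$len)
  set.seed(substream[["derived"]])
  for (i in seq_along(sds)) {
    s <- sds[[i]]
    seg <- anc[[s$parent_chrom]][(s$parent_start + 1L):(s$parent_start + s$len)]
    sds[[i]]$derived_seq <- mutate_raw(seg, config$derived_extra_divergence)
  }

  ## splice events into B, tracking derived (B) coordinates
  edits <- stats::setNames(vector("list", length(chroms)), chroms)
  push_edit <- function(chrom, edit) {
    edits[[chrom]] <<- c(edits[[chrom]], list(edit))
  }
  for (i in seq_along(events)) {
    ev <- events[[i]]
    ev$id <- sprintf("sv%03d", i)
    push_edit(ev$chrom, ev)
  }
  for (i in seq_along(sds)) {
    s <- sds[[i]]
    push_edit(s$target_chrom,
              list(kind = "SDINS", chrom = s$target_chrom,
                   start = s$target_pos, end = s$target_pos,
                   len = s$len, insseq = s$derived_seq,
                   id = sprintf("sd%03d", i), sd_index = i))
  }

  truth <- list()
  add_truth <- function(chrom, start, end, id, kind, direction, role, len,
                        boundary) {
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      event_id = id, kind = kind, direction = direction, role = role,
      length = as.integer(len), boundary_flag = boundary,
      stringsAsFactors = FALSE)
  }

  for (chrom in chroms) {
    evs <- edits[[chrom]]
    if (length(evs) == 0L) next
    ord <- order(vapply(evs, function(e) e$start, numeric(1)))
    evs <- evs[ord]
    src <- bseq[[chrom]]
    pieces <- list()
    cursor <- 0L   # 0-based position consumed in ancestral coords
    bpos <- 0L     # current length of assembled B
    emit <- function(x) {
      pieces[[length(pieces) + 1L]] <<- x
      bpos <<- bpos + length(x)
    }
    for (ev in evs) {
      if (ev$start > cursor) emit(src[(cursor + 1L):ev$start])
      b_at <- bpos
      switch(ev$kind,
        DEL = {
          add_truth(chrom, ev$start, ev$end, ev$id, "DEL", NA_character_,
                    "sv", ev$len, NA)
          cursor <- ev$end
        },
        INS = {
          emit(ev$insseq)
          add_truth(chrom, ev$start, ev$start, ev$id, "INS", NA_character_,
                    "sv", ev$len, NA)
          cursor <- ev$start
        },
        DUP = {
          seg <- src[(ev$start + 1L):ev$end]
          emit(seg); emit(seg)
          add_truth(chrom, ev$start, ev$end, ev$id, "DUP", NA_character_,
                    "sv", ev$len, NA)
          cursor <- ev$end
        },
        INV = {
          emit(revcomp_raw(src[(ev$start + 1L):ev$end]))
          add_truth(chrom, ev$start, ev$end, ev$id, "INV", NA_character_,
                    "sv", ev$len, NA)
          cursor <- ev$end
        },
        SDINS = {
          emit(ev$insseq)
          s <- sds[[ev$sd_index]]
          add_truth(s$parent_chrom, s$parent_start, s$parent_start + s$len,
                    ev$id, "SD", s$direction, "parent", s$len, FALSE)
          add_truth(chrom, b_at, b_at + s$len, ev$id, "SD", s$direction,
                    "derived", s$len, TRUE)
          cursor <- ev$start
        })
    }
    if (cursor < length(src)) emit(src[(cursor + 1L):length(src)])
    bseq[[chrom]] <- unlist(pieces)
  }

  ## assembly A: ancestral plus N-gap overwrites
  aseq <- anc
  for (g in ngaps) {
    aseq[[g$chrom]][(g$start + 1L):g$end] <- charToRaw("N")
  }

  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  a <- Biostrings::DNAStringSet(vapply(aseq, rawToChar, character(1)))
  b <- Biostrings::DNAStringSet(vapply(bseq, rawToChar, character(1)))
  names(a) <- names(b) <- chroms
  structure(list(a = a, b = b, truth = truth, x_name = config$x_name,
                 config = config),
            class = "assembly_pair")
}

#' @export
print.assembly_pair <- function(x, ...) {
  cat("assembly pair:", length(x$a), "chromosomes,",
      sum(as.numeric(Biostrings::width(x$a))), "bp (A) /",
      sum(as.numeric(Biostrings::width(x$b))), "bp (B),",
      nrow(x$truth), "truth rows\n")
  invisible(x)
}

#' Write or read a planted-event truth table
#'
#' Truth tables are BED-like TSVs (0-based half-open) with columns
#' `chrom`, `start`, `end`, `event_id`, `kind`, `direction`, `role`,
#' `length`, `boundary_flag`; they round-trip losslessly.
#'
#' @param records truth data frame as produced by [simulate_pair()].
#' @param path output (or input) file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns
#'   the truth data frame.
#' @export
write_truth <- function(records, path) {
  cols <- c("chrom", "start", "end", "event_id", "kind", "direction",
            "role", "length", "boundary_flag")
  if (nrow(records) == 0L) records <- empty_truth()
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                   colClasses = c(chrom = "character", start = "integer",
                                  end = "integer", event_id = "character",
                                  kind = "character", direction = "character",
                                  role = "character", length = "integer",
                                  boundary_flag = "logical"),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_truth())
  df
}

#' Maximal N-runs of an assembly
#'
#' @param assembly a [Biostrings::DNAStringSet].
#' @return data frame `chrom`, `start`, `end` (0-based half-open) of
#'   maximal runs of `N`/`n`.
#' @export
n_runs <- function(assembly) {
  out <- lapply(names(assembly), function(chrom) {
    m <- Biostrings::matchPattern("N", assembly[[chrom]], fixed = TRUE)
    r <- IRanges::reduce(as(m, "IRanges"))
    if (length(r) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer()))
    data.frame(chrom = chrom, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
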