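#' Pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()]. Either a
#' simulation configuration (`sim`) or a pair of FASTA paths (or a
#' precomputed PAF) must be supplied. Every stage parameter defaults to
#' the corresponding module default. Configurations round-trip through
#' [save_run_config()] / [load_run_config()] as flat key=value files.
#'
#' @param out_dir output directory for all artifacts.
#' @param sim optional [sim_config()]; when given, the pair is simulated.
#' @param fasta_a,fasta_b optional FASTA paths for the two assemblies.
#' @param paf optional precomputed PAF path (assembly A as query).
#' @param annotation optional GFF3/BED gene annotation (copy-side
#'   coordinates).
#' @param x_name X-chromosome name, or `NA`.
#' @param k,min_block,gap_tol,max_anchor_gap,max_target_hits aligner
#'   parameters, see [anchor_chain_align()].
#' @param min_identity one-to-one identity threshold.
#' @param min_len SV length filter (bp).
#' @param boundary_tol bSD boundary tolerance (bp).
#' @param ne_factor Ne adjustment for X expectations.
#' @param seed integer seed (used by the simulation stage).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, fasta_a = NULL, fasta_b = NULL,
                       paf = NULL, annotation = NULL,
                       x_name = NA_character_, k = 21L, min_block = 1000L,
                       gap_tol = 100L, max_anchor_gap = 500L,
                       max_target_hits = 4L, min_identity = 0.90,
                       min_len = 1000L, boundary_tol = 1000L,
                       ne_factor = 0.75, seed = 1L) {
  if (is.null(sim) && (is.null(fasta_a) || is.null(fasta_b)))
    stop("either a simulation config or two FASTA paths are required")
  structure(list(out_dir = out_dir, sim = sim, fasta_a = fasta_a,
                 fasta_b = fasta_b, paf = paf, annotation = annotation,
                 x_name = x_name, k = as.integer(k),
                 min_block = as.integer(min_block),
                 gap_tol = as.integer(gap_tol),
                 max_anchor_gap = as.integer(max_anchor_gap),
                 max_target_hits = as.integer(max_target_hits),
                 min_identity = min_identity, min_len = as.integer(min_len),
                 boundary_tol = as.integer(boundary_tol),
                 ne_factor = ne_factor, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full assembly-comparison pipeline
#'
#' Executes simulate (optional) -> align -> synteny -> structural
#' variants -> segmental duplications -> X-versus-autosome statistics,
#' writing TSV/JSON artifacts and a manifest with parameter values and
#' file checksums. Identical configuration and seed give identical
#' checksums. Any stage error aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages?
#' @return list with the in-memory results of every stage and the
#'   manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  art <- function(name) file.path(config$out_dir, name)
  files <- character(0)
  note <- function(path) files <<- c(files, path)

  ## stage: simulate / load
  truth <- NULL
  if (!is.null(config$sim)) {
    say("simulate", "simulating assembly pair (seed ", config$sim$seed, ")")
    pair <- step("simulate", simulate_pair(config$sim))
    a <- pair$a; b <- pair$b; truth <- pair$truth
    x_name <- pair$x_name
    step("simulate", {
      Biostrings::writeXStringSet(a, art("assembly_A.fa"))
      Biostrings::writeXStringSet(b, art("assembly_B.fa"))
      write_truth(truth, art("truth.tsv"))
    })
    note(art("truth.tsv"))
  } else {
    say("load", "reading assemblies")
    a <- step("load", Biostrings::readDNAStringSet(config$fasta_a))
    b <- step("load", Biostrings::readDNAStringSet(config$fasta_b))
    names(a) <- sub("\\s.*", "", names(a))
    names(b) <- sub("\\s.*", "", names(b))
    x_name <- config$x_name
  }

  ## stage: align
  blocks <- if (!is.null(config$paf)) {
    say("align", "reading alignments from ", config$paf)
    step("align", read_paf(config$paf))
  } else {
    say("align", "anchor-chain alignment (k=", config$k, ")")
    step("align", anchor_chain_align(a, b, k = config$k,
                                     min_block = config$min_block,
                                     gap_tol = config$gap_tol,
                                     max_anchor_gap = config$max_anchor_gap,
                                     max_target_hits = config$max_target_hits))
  }
  step("align", write_paf(blocks, art("alignments.paf")))
  note(art("alignments.paf"))

  ## stage: synteny
  say("synteny", "one-to-one map and continuity statistics")
  synteny <- step("synteny", one_to_one_map(blocks,
                                            min_identity = config$min_identity))
  step("synteny", write.table(as.data.frame(synteny), art("synteny.tsv"),
                              sep = "\t", quote = FALSE, row.names = FALSE))
  note(art("synteny.tsv"))
  gaps <- step("synteny", n_runs(a))
  gap_report <- step("synteny", gap_fill_stats(gaps, b, synteny))
  lr <- step("synteny", suppressWarnings(gapless_length_ratio(a, b)))
  step("synteny", {
    write.table(gap_report$per_chrom, art("gap_fill.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(lr, art("length_ratio.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  note(art("gap_fill.tsv")); note(art("length_ratio.tsv"))

  ## stage: structural variants
  say("sv", "classifying structural variants")
  svs <- step("sv", suppressWarnings(
    classify_svs(synteny, blocks, a, b, dup_min_len = config$min_block)))
  svs_kept <- step("sv", filter_svs(svs, min_len = config$min_len))
  chroms <- chrom_table(a, x_name)
  sv_counts <- step("sv", count_by_chromosome(svs_kept, chroms))
  step("sv", {
    write_sv_tsv(svs_kept, art("svs.tsv"))
    write_sv_vcf(svs_kept, a, art("svs.vcf"))
    write.table(as.data.frame(sv_counts), art("sv_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  note(art("svs.tsv")); note(art("svs.vcf")); note(art("sv_counts.tsv"))

  ## stage: segmental duplications
  say("sd", "detecting segmental duplications")
  pairs <- step("sd", find_many_to_one(blocks, min_len = config$min_block))
  pairs <- pairs[pairs$copy1_chrom != pairs$copy2_chrom, , drop = FALSE]
  pairs <- step("sd", classify_sd(pairs, synteny,
                                  boundary_tol = config$boundary_tol))
  pairs <- step("sd", resolve_parent(pairs, assembly_copy = b,
                                     assembly_anchor = a, x_name = x_name))
  sd_dir <- step("sd", categorize_direction(pairs, chroms))
  genes <- NULL
  if (!is.null(config$annotation)) {
    ann <- step("sd", read_gene_annotation(config$annotation))
    genes <- step("sd", genes_in_derived(pairs, ann,
                                         known_chroms = chroms$chrom))
    writeLines(attr(genes, "all_genes"), art("derived_genes.txt"))
    note(art("derived_genes.txt"))
  }
  step("sd", {
    write.table(as.data.frame(pairs), art("sd_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(sd_dir$counts), art("sd_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note(art("sd_pairs.tsv")); note(art("sd_counts.tsv"))

  ## stage: chromosome statistics
  deviations <- list()
  n_autosomes <- sum(!chroms$is_x)
  if (!is.na(x_name) && n_autosomes >= 3L) {
    say("stats", "X-versus-autosome regression")
    x_len <- chroms$length[chroms$is_x]
    for (cat in SV_TYPES) {
      x_obs <- sv_counts[[cat]][sv_counts$is_x]
      fit <- try(fit_autosome_regression(sv_counts, cat), silent = TRUE)
      if (!inherits(fit, "try-error"))
        deviations[[cat]] <- try(x_deviation(fit, x_len, x_obs,
                                             ne_factor = config$ne_factor),
                                 silent = TRUE)
    }
    dev_df <- do.call(rbind, lapply(deviations, function(d) {
      if (inherits(d, "try-error")) return(NULL)
      data.frame(category = d$category, slope = d$slope,
                 intercept = d$intercept, r_squared = d$r_squared,
                 x_observed = d$x_observed, x_predicted = d$x_predicted,
                 x_expected_adjusted = d$x_expected_adjusted,
                 deviation_pct = d$deviation_pct,
                 deviation_pct_unadjusted = d$deviation_pct_unadjusted,
                 p_value = d$p_value)
    }))
    if (!is.null(dev_df)) {
      write.table(dev_df, art("x_deviation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      note(art("x_deviation.tsv"))
    }
  } else {
    say("stats", "skipped (no X chromosome or fewer than 3 autosomes)")
  }

  ## truth-based evaluation when simulating
  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- list(
      sv = evaluate_sv_calls(svs_kept, truth),
      sd = evaluate_sd_directions(pairs, truth))
    say("report", sprintf("SV recall %.3f, precision %.3f",
                          evaluation$sv$recall, evaluation$sv$precision))
  }

  manifest <- list(
    package_version = as.character(packageVersion("asmpair")),
    seed = config$seed,
    parameters = config[c("k", "min_block", "gap_tol", "max_anchor_gap",
                          "max_target_hits", "min_identity", "min_len",
                          "boundary_tol", "ne_factor")],
    x_name = x_name,
    artifacts = lapply(stats::setNames(files, basename(files)),
                       function(f) list(path = basename(f),
                                        md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(assembly_a = a, assembly_b = b, truth = truth,
                 blocks = blocks, synteny = synteny,
                 gap_report = gap_report, length_ratio = lr,
                 svs = svs_kept, sv_counts = sv_counts, sd_pairs = pairs,
                 sd_counts = sd_dir, genes = genes,
                 deviations = deviations, evaluation = evaluation,
                 manifest = manifest))
}

#' Save or load a pipeline configuration as a flat key=value file
#'
#' Simulation sub-configurations are inlined with a `sim.` prefix;
#' vector values are comma-separated.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config`
#'   a `run_config`.
#' @export
save_run_config <- function(config, path) {
  flat <- list()
  put <- function(key, val) {
    if (is.null(val)) return()
    flat[[key]] <<- paste(val, collapse = ",")
  }
  for (key in setdiff(names(config), "sim")) put(key, config[[key]])
  if (!is.null(config$sim)) {
    s <- config$sim
    put("sim.seed", s$seed)
    put("sim.chrom_names", names(s$chrom_lengths))
    put("sim.chrom_lengths", s$chrom_lengths)
    put("sim.x_name", s$x_name)
    put("sim.background_divergence", s$background_divergence)
    put("sim.sv_rates", s$sv_rates)
    put("sim.sv_length_range", s$sv_length_range)
    put("sim.sd_counts", s$sd_counts)
    put("sim.sd_length_range", s$sd_length_range)
    put("sim.derived_extra_divergence", s$derived_extra_divergence)
    put("sim.ngap_count", s$ngap_count)
    put("sim.ngap_length_range", s$ngap_length_range)
    put("sim.margin", s$margin)
  }
  writeLines(paste0(names(flat), "=", unlist(flat)), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  get <- function(key, as = identity, default = NULL) {
    if (!key %in% keys) return(default)
    v <- strsplit(vals[match(key, keys)], ",", fixed = TRUE)[[1]]
    as(v)
  }
  num1 <- function(v) as.numeric(v)[1]
  sim <- NULL
  if ("sim.seed" %in% keys) {
    lens <- get("sim.chrom_lengths", as.numeric)
    names(lens) <- get("sim.chrom_names")
    sim <- sim_config(
      seed = get("sim.seed", num1),
      chrom_lengths = lens,
      x_name = get("sim.x_name", identity, NA_character_),
      background_divergence = get("sim.background_divergence", num1, 0.001),
      sv_rates = stats::setNames(get("sim.sv_rates", as.numeric,
                                     c(3, 3, 2, 2)),
                                 c("DEL", "INS", "DUP", "INV")),
      sv_length_range = get("sim.sv_length_range", as.numeric,
                            c(200, 50000)),
      sd_counts = stats::setNames(get("sim.sd_counts", as.numeric,
                                      c(4, 4, 4)),
                                  c("A>A", "A>X", "X>A")),
      sd_length_range = get("sim.sd_length_range", as.numeric,
                            c(2000, 10000)),
      derived_extra_divergence = get("sim.derived_extra_divergence",
                                     num1, 0.02),
      ngap_count = get("sim.ngap_count", num1, 5),
      ngap_length_range = get("sim.ngap_length_range", as.numeric,
                              c(500, 3000)),
      margin = get("sim.margin", num1, 2500))
  }
  run_config(
    out_dir = get("out_dir"),
    sim = sim,
    fasta_a = get("fasta_a"), fasta_b = get("fasta_b"),
    paf = get("paf"), annotation = get("annotation"),
    x_name = get("x_name", identity, NA_character_),
    k = get("k", num1, 21), min_block = get("min_block", num1, 1000),
    gap_tol = get("gap_tol", num1, 100),
    max_anchor_gap = get("max_anchor_gap", num1, 500),
    max_target_hits = get("max_target_hits", num1, 4),
    min_identity = get("min_identity", num1, 0.90),
    min_len = get("min_len", num1, 1000),
    boundary_tol = get("boundary_tol", num1, 1000),
    ne_factor = get("ne_factor", num1, 0.75),
    seed = get("seed", num1, 1))
}
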