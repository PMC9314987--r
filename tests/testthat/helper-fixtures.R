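# Shared fixture builders (all inputs are generated in code).

quiet_cfg <- function(seed, chrom_lengths, ...) {
  defaults <- list(seed = seed, chrom_lengths = chrom_lengths,
                   background_divergence = 0,
                   sv_rates = c(DEL = 0, INS = 0, DUP = 0, INV = 0),
                   sd_counts = c("A>A" = 0, "A>X" = 0, "X>A" = 0),
                   ngap_count = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# a minimal synteny_blocks data frame built by hand
make_synteny <- function(query_name, query_start, query_end, strand,
                         target_name, target_start, target_end,
                         chain_id, identity = 1) {
  n <- length(query_start)
  bl <- pmax(query_end - query_start, target_end - target_start)
  df <- data.frame(
    query_name = query_name, query_len = 10e6,
    query_start = query_start, query_end = query_end,
    strand = strand, target_name = target_name, target_len = 10e6,
    target_start = target_start, target_end = target_end,
    matches = round(identity * bl), block_length = bl,
    identity = identity, mapq = 255L, tags = "",
    chain_id = chain_id, stringsAsFactors = FALSE)
  span <- tapply(df$block_length, df$chain_id, sum)
  df$chain_span <- as.numeric(span[as.character(df$chain_id)])
  class(df) <- c("synteny_blocks", "data.frame")
  df
}

make_blocks <- function(query_name, query_start, query_end, strand,
                        target_name, target_start, target_end,
                        matches = NULL, seq_len = 10e6) {
  bl <- pmax(query_end - query_start, target_end - target_start)
  if (is.null(matches)) matches <- bl
  alignment_blocks(data.frame(
    query_name = query_name, query_len = seq_len,
    query_start = query_start, query_end = query_end,
    strand = strand, target_name = target_name, target_len = seq_len,
    target_start = target_start, target_end = target_end,
    matches = matches, block_length = bl, stringsAsFactors = FALSE))
}
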