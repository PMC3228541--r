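# Independent oracles and small fixture builders shared across the suite.

# Brute-force k-mer counter: explicit position loop with an environment
# accumulator, reverse complements taken from Biostrings rather than the
# package's own routine. Deliberately naive and independent of the
# implementation it checks.
oracle_profile <- function(records, k, include_revcomp = TRUE) {
  counts <- new.env(parent = emptyenv())
  seqs <- records$seq
  if (include_revcomp && length(seqs)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)
    ))
    seqs <- c(seqs, rc)
  }
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[NX]", w)) next
      prev <- if (exists(w, envir = counts, inherits = FALSE)) {
        get(w, envir = counts)
      } else 0
      assign(w, prev + 1, envir = counts)
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) out <- stats::setNames(numeric(0), character(0))
  out[order(names(out))]
}

# Binary-dissemination bound: with unit per-host concurrency, uniform
# links and simultaneous boots, the number of payload holders doubles
# each round, so n recipients finish in ceiling(log2(n + 1)) rounds.
oracle_rounds <- function(n_workers) ceiling(log2(n_workers + 1))

# Check queue slot conservation on a job-trace log: for every (queue,
# host) the number of overlapping events never exceeds `slots` at any
# event start instant.
max_concurrency <- function(log, queue, host = NULL) {
  ev <- log[log$queue == queue, ]
  if (!is.null(host)) ev <- ev[ev$host == host, ]
  if (nrow(ev) == 0L) return(0L)
  max(vapply(ev$start, function(t) {
    sum(ev$start <= t + 1e-12 & ev$end > t + 1e-12)
  }, integer(1)))
}

# A context with deterministic boots (no latency, no jitter) for exact
# scheduling arithmetic, plus a registered credential.
quiet_context <- function(seed = 1L, provider_cap = 20L, ...) {
  ctx <- elastiseq_context(
    seed = seed, provider_cap = provider_cap,
    boot_latency = 0, boot_jitter = 0, ...
  )
  add_credential(ctx, "acct")
  ctx
}

# Write a small synthetic query/reference pair and return a filled-in
# search-protocol config.
search_fixture <- function(dir, n_query = 40L, n_ref = 15L, seed = 5L,
                           k = 5, beta = 0.5, alpha = 0.5, mode = "local",
                           query_len = c(150L, 250L), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- generate_synthetic(n_query, query_len[1], query_len[2],
                          seed = seed, prefix = "q")
  r <- generate_synthetic(n_ref, 300, 400, seed = seed + 1L, prefix = "ref")
  write_fasta(q, file.path(dir, "query.fasta"))
  write_fasta(r, file.path(dir, "reference.fasta"))
  cfg <- describe_protocol(elastiseq_context(), "search")
  cfg$inputs$query <- file.path(dir, "query.fasta")
  cfg$inputs$reference <- file.path(dir, "reference.fasta")
  cfg$params$k <- as.character(k)
  cfg$params$alpha <- as.character(alpha)
  cfg$params$beta <- as.character(beta)
  cfg$cluster$mode <- mode
  cfg$cluster$credential <- "acct"
  cfg$output$dir <- file.path(dir, paste0("out-", mode))
  extra <- list(...)
  for (nm in names(extra)) cfg$params[[nm]] <- as.character(extra[[nm]])
  cfg
}
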