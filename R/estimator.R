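#' K-mer profile of a sequence set
#'
#' Counts every length-`k` word of every sequence by sliding window. For DNA
#' the reverse-complemented strand is counted as well by default, so the
#' profile is strand-symmetric. Windows containing ambiguity codes (N for
#' dna, X for protein) are skipped; sequences shorter than `k` contribute
#' nothing.
#'
#' Defaults follow the search-runtime estimation convention: k = 11 for DNA
#' (both strands), k = 3 for protein (single strand).
#'
#' @param records a `seq_records` tibble.
#' @param k word length in residues (>= 1); default 11 for dna, 3 for
#'   protein.
#' @param include_revcomp also count each sequence's reverse complement.
#'   Only allowed for dna; defaults to `TRUE` for dna.
#' @return an object of class `kmer_profile`: list with `k`, `alphabet`,
#'   `include_revcomp`, `counts` (named numeric vector) and `total`
#'   (sum of counts).
#' @export
kmer_profile <- function(records, k = NULL, include_revcomp = NULL) {
  validate_records(records)
  alphabet <- if (nrow(records)) records$alphabet[1] else "dna"
  if (is.null(k)) k <- if (alphabet == "dna") 11L else 3L
  k <- as.integer(k)
  if (k < 1L) abort("k must be >= 1")
  if (is.null(include_revcomp)) include_revcomp <- alphabet == "dna"
  if (include_revcomp && alphabet != "dna") {
    abort("include_revcomp applies to dna profiles only")
  }
  seqs <- records$seq
  if (include_revcomp && length(seqs)) {
    seqs <- c(seqs, reverse_complement(seqs))
  }
  ambiguity <- if (alphabet == "dna") "N" else "X"
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq.int(k, n))
  }), use.names = FALSE)
  if (length(words)) {
    words <- words[!grepl(ambiguity, words, fixed = TRUE)]
  }
  counts <- if (length(words)) {
    tab <- table(words)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(
    list(
      k = k, alphabet = alphabet, include_revcomp = include_revcomp,
      counts = counts, total = sum(counts)
    ),
    class = "kmer_profile"
  )
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf(
    "<kmer_profile> k=%d %s%s: %d distinct words, total %g\n",
    x$k, x$alphabet, if (x$include_revcomp) " (+revcomp)" else "",
    length(x$counts), x$total
  ))
  invisible(x)
}

#' Per-word reference weights from a reference-database profile
#'
#' The default weighting used by the runtime model: each k-mer's weight is
#' its relative frequency in the reference profile, so the overlap statistic
#' measures how much of the query's word content the database is dense in.
#'
#' @param reference a `kmer_profile` of the reference database.
#' @return named numeric vector of weights summing to 1 (empty reference
#'   gives an empty weight map).
#' @export
reference_weights <- function(reference) {
  stopifnot(inherits(reference, "kmer_profile"))
  if (reference$total == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  reference$counts / reference$total
}

#' Overlap statistic between a query profile and reference weights
#'
#' The scalar the timing model is linear in:
#' \eqn{x = \sum_w c_q(w)\, \omega_{ref}(w)} — the dot product of query
#' k-mer counts with per-k-mer reference weights (words absent from the
#' weight map contribute 0). Linear and monotone in every query count.
#'
#' @param query a `kmer_profile`.
#' @param weights named numeric vector of per-k-mer weights.
#' @param k if given, checked against `query$k`.
#' @return non-negative scalar.
#' @export
overlap_statistic <- function(query, weights, k = NULL) {
  stopifnot(inherits(query, "kmer_profile"))
  if (!is.null(k) && query$k != k) {
    abort(sprintf("k mismatch: query profile has k=%d, model has k=%d", query$k, k))
  }
  if (length(query$counts) == 0L || length(weights) == 0L) return(0)
  shared <- intersect(names(query$counts), names(weights))
  if (length(shared) == 0L) return(0)
  sum(query$counts[shared] * weights[shared])
}

#' Fit the linear runtime model from timed calibration runs
#'
#' Ordinary least squares of observed CPU-hours on the overlap statistic:
#' \eqn{t \approx \alpha + \beta x}. A negative fitted intercept is
#' meaningless (fixed cost cannot be negative), so alpha is clamped at 0 and
#' beta refit through the origin in that case.
#'
#' @param runs a data frame with columns `overlap` (x) and `cpu_hours`
#'   (observed time); at least 2 rows with distinct x.
#' @param k word length the model applies to.
#' @param weights the reference weight map used to compute `overlap`.
#' @param alphabet `"dna"` or `"protein"`.
#' @return an object of class `runtime_model`: `k`, `alphabet`, `weights`,
#'   `alpha`, `beta`, plus the fit residual standard error.
#' @export
fit_runtime_model <- function(runs, k, weights, alphabet = "dna") {
  stopifnot(all(c("overlap", "cpu_hours") %in% names(runs)))
  if (nrow(runs) < 2L) abort("need at least 2 calibration runs")
  if (length(unique(runs$overlap)) < 2L) {
    abort("calibration runs must span at least 2 distinct overlap values")
  }
  fit <- stats::lm(cpu_hours ~ overlap, data = runs)
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  if (alpha < 0) {
    fit <- stats::lm(cpu_hours ~ 0 + overlap, data = runs)
    alpha <- 0
    beta <- unname(stats::coef(fit)[1])
  }
  structure(
    list(
      k = as.integer(k), alphabet = alphabet, weights = weights,
      alpha = alpha, beta = beta,
      sigma = stats::sigma(fit), n_runs = nrow(runs)
    ),
    class = "runtime_model"
  )
}

#' Build a runtime model directly from known coefficients
#'
#' Convenience constructor for protocols that ship pre-calibrated
#' coefficients with a pre-calculated reference profile.
#'
#' @param alpha fixed-overhead CPU-hours (>= 0).
#' @param beta CPU-hours per unit of overlap.
#' @param weights named numeric weight map.
#' @param k word length.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a `runtime_model`.
#' @export
runtime_model <- function(alpha, beta, weights, k, alphabet = "dna") {
  if (alpha < 0) abort("alpha must be >= 0")
  structure(
    list(
      k = as.integer(k), alphabet = alphabet, weights = weights,
      alpha = alpha, beta = beta, sigma = NA_real_, n_runs = 0L
    ),
    class = "runtime_model"
  )
}

#' Predict CPU-hours for a query workload
#'
#' \eqn{T = \alpha + \beta \cdot x(query)} where x is
#' [overlap_statistic()]. The estimate is the total CPU time of the search,
#' to be divided across partitions and instances by the planner.
#'
#' @param model a `runtime_model`.
#' @param query a `kmer_profile` with matching `k`.
#' @return estimated CPU-hours (>= 0).
#' @export
predict_cpu_hours <- function(model, query) {
  stopifnot(inherits(model, "runtime_model"))
  x <- overlap_statistic(query, model$weights, k = model$k)
  max(0, model$alpha + model$beta * x)
}

#' @export
print.runtime_model <- function(x, ...) {
  cat(sprintf(
    "<runtime_model> k=%d %s: T = %.4g + %.4g * overlap (%d calibration runs)\n",
    x$k, x$alphabet, x$alpha, x$beta, x$n_runs
  ))
  invisible(x)
}

#' Tidy a runtime model's coefficients
#'
#' @param x a `runtime_model`.
#' @param ... unused.
#' @return a tibble with one row per coefficient (`term`, `estimate`).
#' @exportS3Method generics::tidy
#' @export
tidy.runtime_model <- function(x, ...) {
  tibble(
    term = c("alpha (fixed CPU-hours)", "beta (CPU-hours per overlap unit)"),
    estimate = c(x$alpha, x$beta)
  )
}

#' One-row model summary
#'
#' @param x a `runtime_model`.
#' @param ... unused.
#' @return a tibble with `k`, `alphabet`, `alpha`, `beta`, `sigma`, `n_runs`.
#' @exportS3Method generics::glance
#' @export
glance.runtime_model <- function(x, ...) {
  tibble(
    k = x$k, alphabet = x$alphabet, alpha = x$alpha, beta = x$beta,
    sigma = x$sigma, n_runs = x$n_runs
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Serialize / read profiles and models
#'
#' Profiles and models round-trip through a documented JSON text format
#' (`k`, `alphabet`, `include_revcomp`, `counts` for profiles; plus
#' `alpha`, `beta`, `weights` for models).
#'
#' @param x a `kmer_profile` or `runtime_model`.
#' @param path output path.
#' @return `path` invisibly; readers return the reconstructed object.
#' @export
write_profile <- function(x, path) {
  stopifnot(inherits(x, "kmer_profile"))
  jsonlite::write_json(
    list(
      kind = "kmer_profile", k = x$k, alphabet = x$alphabet,
      include_revcomp = x$include_revcomp, counts = as.list(x$counts)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- unlist(j$counts) %||% stats::setNames(numeric(0), character(0))
  structure(
    list(
      k = as.integer(j$k), alphabet = j$alphabet,
      include_revcomp = isTRUE(j$include_revcomp),
      counts = counts, total = sum(counts)
    ),
    class = "kmer_profile"
  )
}

#' @rdname write_profile
#' @export
write_runtime_model <- function(x, path) {
  stopifnot(inherits(x, "runtime_model"))
  jsonlite::write_json(
    list(
      kind = "runtime_model", k = x$k, alphabet = x$alphabet,
      alpha = x$alpha, beta = x$beta, weights = as.list(x$weights)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_profile
#' @export
read_runtime_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(j$weights) %||% stats::setNames(numeric(0), character(0))
  runtime_model(j$alpha, j$beta, w, j$k, j$alphabet)
}
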