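#' Register a dataset with a cluster
#'
#' Datasets are named lists of files accessible by a cluster; user query
#' data, reference data and pipeline outputs are all managed as datasets.
#' Registration records per-file byte sizes and content checksums, which
#' later make transfers idempotent.
#'
#' @param ctx an [elastiseq_context()].
#' @param cluster cluster name (`"local"` for the client machine).
#' @param name dataset name, unique per cluster.
#' @param files existing file paths.
#' @param tags named list of free-form tags.
#' @return the dataset record (list), invisibly.
#' @export
add_dataset <- function(ctx, cluster, name, files, tags = list()) {
  get_cluster(ctx, cluster)
  if (!is.null(ctx$datasets[[cluster]][[name]])) {
    abort(sprintf("dataset '%s' already registered on cluster '%s'", name, cluster))
  }
  if (length(files) == 0L) abort("a dataset needs at least one file")
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    abort(sprintf("missing dataset file(s): %s", paste(missing, collapse = ", ")))
  }
  ds <- list(
    name = name, cluster = cluster, files = files,
    file_bytes = stats::setNames(file.size(files), files),
    checksums = stats::setNames(unname(tools::md5sum(files)), files),
    bytes = sum(file.size(files)),
    tags = tags, producer = NULL
  )
  if (is.null(ctx$datasets[[cluster]])) ctx$datasets[[cluster]] <- list()
  ctx$datasets[[cluster]][[name]] <- ds
  invisible(ds)
}

get_dataset <- function(ctx, cluster, name) {
  ds <- ctx$datasets[[cluster]][[name]]
  if (is.null(ds)) {
    abort(sprintf("no dataset '%s' on cluster '%s'", name, cluster))
  }
  ds
}

#' Transfer a dataset between clusters
#'
#' Synchronization semantics: files whose checksum already matches on the
#' destination are skipped, so an immediate re-transfer moves zero bytes
#' and a transfer after one file changed moves only that file. Transfer
#' time follows the simulated link: desktop-to-cloud transfers use the
#' (slower) local link, intra-cloud transfers the instance-to-instance
#' bandwidth; the virtual clock advances accordingly.
#'
#' @param ctx an [elastiseq_context()].
#' @param name dataset name on the source cluster.
#' @param src,dst cluster names.
#' @return tibble report: one row per file with `file`, `bytes`,
#'   `bytes_moved`, `skipped`, plus attribute `hours` (transfer time).
#' @export
transfer_dataset <- function(ctx, name, src, dst) {
  ds <- get_dataset(ctx, src, name)
  get_cluster(ctx, dst)
  current <- stats::setNames(unname(tools::md5sum(ds$files)), ds$files)
  existing <- ctx$datasets[[dst]][[name]]
  skipped <- if (is.null(existing)) {
    rep(FALSE, length(ds$files))
  } else {
    vapply(ds$files, function(f) {
      identical(unname(existing$checksums[f]), unname(current[f]))
    }, logical(1), USE.NAMES = FALSE)
  }
  bytes_files <- unname(file.size(ds$files))
  bytes <- bytes_files
  moved <- sum(bytes[!skipped])
  local_link <- (src == "local") != (dst == "local")
  mb_s <- if (local_link) ctx$cloud$local_link_mb_s else ctx$cloud$bandwidth_mb_s
  hours <- (moved / 1e6) / (mb_s * 3600)
  cloud_advance(ctx$cloud, ctx$cloud$now + hours)
  ds_dst <- ds
  ds_dst$cluster <- dst
  ds_dst$checksums <- current
  ds_dst$producer <- ds$producer
  ctx$datasets[[dst]][[name]] <- ds_dst
  report <- tibble(
    file = ds$files, bytes = bytes,
    bytes_moved = ifelse(skipped, 0, bytes), skipped = skipped
  )
  attr(report, "hours") <- hours
  report
}

#' Describe a dataset
#'
#' Read-only metadata including provenance: datasets produced by a
#' pipeline carry the producing pipeline id, protocol id/version and the
#' parameter snapshot used.
#'
#' @param ctx an [elastiseq_context()].
#' @param name dataset name.
#' @param cluster cluster name.
#' @return list: `name`, `cluster`, `files`, `bytes`, `tags`, `producer`
#'   (NULL for user-registered data).
#' @export
describe_dataset <- function(ctx, name, cluster = "local") {
  ds <- get_dataset(ctx, cluster, name)
  ds[c("name", "cluster", "files", "file_bytes", "bytes", "tags", "producer")]
}

#' Mirror a reference resource into a local store exactly once
#'
#' Reference data is fetched the first time it is accessed and cached with
#' a recorded checksum; later calls return the cached path moving zero
#' bytes. A corrupted cache (checksum mismatch) triggers a re-fetch.
#'
#' @param name resource name (cache key).
#' @param source path to the authoritative copy.
#' @param store local cache directory.
#' @return list: `path` (cached copy), `bytes_moved`.
#' @export
mirror_reference_once <- function(name, source, store) {
  if (!file.exists(source)) abort(sprintf("unresolvable source: %s", source))
  dir.create(store, showWarnings = FALSE, recursive = TRUE)
  cached <- file.path(store, name)
  manifest <- file.path(store, paste0(name, ".md5"))
  if (file.exists(cached) && file.exists(manifest)) {
    want <- readLines(manifest, warn = FALSE)[1]
    have <- unname(tools::md5sum(cached))
    if (identical(want, have)) {
      return(list(path = cached, bytes_moved = 0))
    }
  }
  file.copy(source, cached, overwrite = TRUE)
  writeLines(unname(tools::md5sum(cached)), manifest)
  list(path = cached, bytes_moved = file.size(source))
}

# ---- protocols -------------------------------------------------------------

builtin_protocols <- function() {
  search_params <- tibble(
    name = c("k", "alphabet", "target_hours", "partition_mode",
             "alpha", "beta", "seed"),
    type = c("integer", "character", "numeric", "character",
             "numeric", "numeric", "integer"),
    default = c("11", "dna", "2", "corrected", "0.5", "2.0", "1"),
    required = FALSE
  )
  generic_params <- tibble(
    name = "seed", type = "integer", default = "1", required = FALSE
  )
  list(
    search = list(
      id = "search", version = "1.0",
      params = search_params,
      input_slots = c("query", "reference")
    ),
    microbe = list(
      id = "microbe", version = "1.0",
      params = dplyr::bind_rows(
        generic_params,
        tibble(name = "traits", type = "character", default = "", required = FALSE)
      ),
      input_slots = "reads"
    ),
    sixteen_s = list(
      id = "sixteen_s", version = "1.0",
      params = generic_params, input_slots = "reads"
    ),
    metagenomics = list(
      id = "metagenomics", version = "1.0",
      params = generic_params, input_slots = "reads"
    )
  )
}

#' Describe a protocol as a configuration template
#'
#' Returns a `pipeline_config` pre-filled with every parameter at its
#' default, the required input slots left blank, and the cluster section
#' defaulting to local execution. Write it with [write_config()], edit,
#' and feed to [run_pipeline()].
#'
#' @param ctx an [elastiseq_context()].
#' @param id protocol id.
#' @return a `pipeline_config` list.
#' @export
describe_protocol <- function(ctx, id) {
  proto <- ctx$protocols[[id]]
  if (is.null(proto)) abort(sprintf("unknown protocol '%s'", id))
  params <- as.list(stats::setNames(proto$params$default, proto$params$name))
  inputs <- as.list(stats::setNames(rep("", length(proto$input_slots)),
                                    proto$input_slots))
  pipeline_config(
    protocol = id, version = proto$version, inputs = inputs, params = params,
    cluster = list(credential = "", mode = "local", user_cap = "",
                   instance_type = "c1.xlarge"),
    output = list(dir = "")
  )
}

#' Construct a pipeline configuration
#'
#' @param protocol protocol id.
#' @param version protocol version string.
#' @param inputs named list of input-slot values (dataset names or paths).
#' @param params named list of parameter overrides (stored as strings, as
#'   in the file dialect).
#' @param cluster named list: `credential`, `mode` (`"local"`/`"cloud"`),
#'   `user_cap`, `instance_type`.
#' @param output named list: `dir`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol, version = "1.0", inputs = list(),
                            params = list(), cluster = list(), output = list()) {
  structure(
    list(
      protocol = protocol, version = version,
      inputs = lapply(inputs, as.character),
      params = lapply(params, as.character),
      cluster = utils::modifyList(
        list(credential = "", mode = "local", user_cap = "",
             instance_type = "c1.xlarge"),
        lapply(cluster, as.character)
      ),
      output = utils::modifyList(list(dir = ""), lapply(output, as.character))
    ),
    class = "pipeline_config"
  )
}

#' Read / write the sectioned key=value configuration dialect
#'
#' The pipeline specification file format: INI-style sections
#' `[pipeline]`, `[input]`, `[params]`, `[cluster]`, `[output]`, with
#' `key=value` lines and `#` comments. `parse_config(write_config(x))`
#' reproduces `x` exactly. Unknown sections are rejected here; unknown
#' keys are rejected against the protocol template by
#' [validate_config()].
#'
#' @param path file path (or, for `parse_config`, a character vector of
#'   lines via `text`).
#' @param text optional character vector of config lines instead of a
#'   file.
#' @return `parse_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
parse_config <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list(
    pipeline = list(), input = list(), params = list(),
    cluster = list(), output = list()
  )
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!current %in% names(sections)) {
        abort(sprintf("unknown config section [%s]", current))
      }
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) abort("key=value line before any [section]")
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      sections[[current]][[key]] <- val
    } else {
      abort(sprintf("unparseable config line: '%s'", ln))
    }
  }
  if (is.null(sections$pipeline$protocol)) {
    abort("config must set protocol= in the [pipeline] section")
  }
  pipeline_config(
    protocol = sections$pipeline$protocol,
    version = sections$pipeline$version %||% "1.0",
    inputs = sections$input, params = sections$params,
    cluster = sections$cluster, output = sections$output
  )
}

#' @rdname parse_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fmt <- function(section) {
    vapply(names(section), function(k) sprintf("%s=%s", k, section[[k]]),
           character(1))
  }
  lines <- c(
    "[pipeline]",
    sprintf("protocol=%s", config$protocol),
    sprintf("version=%s", config$version),
    "[input]", fmt(config$inputs),
    "[params]", fmt(config$params),
    "[cluster]", fmt(config$cluster),
    "[output]", fmt(config$output)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Validate a configuration against its protocol template
#'
#' Rejects unknown protocol ids, unknown parameter keys, unknown input
#' slots, bad cluster keys and missing required inputs. Returns the merged
#' configuration (template defaults overlaid with the given overrides).
#'
#' @param ctx an [elastiseq_context()].
#' @param config a `pipeline_config`.
#' @return the merged `pipeline_config`.
#' @export
validate_config <- function(ctx, config) {
  proto <- ctx$protocols[[config$protocol]]
  if (is.null(proto)) abort(sprintf("unknown protocol '%s'", config$protocol))
  bad <- setdiff(names(config$params), proto$params$name)
  if (length(bad)) {
    abort(sprintf("unknown parameter key(s): %s", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(names(config$inputs), proto$input_slots)
  if (length(bad)) {
    abort(sprintf("unknown input slot(s): %s", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(names(config$cluster),
                 c("credential", "mode", "user_cap", "instance_type"))
  if (length(bad)) {
    abort(sprintf("unknown cluster key(s): %s", paste(bad, collapse = ", ")))
  }
  if (!config$cluster$mode %in% c("local", "cloud")) {
    abort(sprintf("cluster mode must be 'local' or 'cloud', not '%s'",
                  config$cluster$mode))
  }
  missing <- setdiff(proto$input_slots, names(config$inputs))
  blank <- names(config$inputs)[!nzchar(unlist(config$inputs))]
  missing <- union(missing, blank)
  if (length(missing)) {
    abort(sprintf("missing required input(s): %s", paste(missing, collapse = ", ")))
  }
  defaults <- as.list(stats::setNames(proto$params$default, proto$params$name))
  merged <- utils::modifyList(defaults, config$params)
  config$params <- merged
  config$version <- proto$version
  config
}

# Typed access to string-stored parameters.
param_num <- function(config, name) as.numeric(config$params[[name]])
param_int <- function(config, name) as.integer(config$params[[name]])
param_chr <- function(config, name) as.character(config$params[[name]])
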