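PHASE_NAMES <- c(
  "validate", "start_cluster", "upload", "execute",
  "monitor", "download", "postprocess"
)

new_phase_table <- function() {
  tibble(
    phase = seq_along(PHASE_NAMES), name = PHASE_NAMES,
    status = "pending", start = NA_real_, end = NA_real_
  )
}

#' Run a pipeline from a configuration
#'
#' The wrapper state machine: seven phases executed in fixed order —
#' (1) pre-processing and validation, (2) start cluster, (3) upload,
#' (4) execute the worker workload, (5) monitor (including scaling and
#' idle termination), (6) download, (7) post-processing. In local mode
#' phases 2, 3 and 6 are marked `skipped` and perform no backend calls;
#' the worker runs on the local cluster's CPU slots. A validation failure
#' halts the run before any instance is started; a later failure still
#' triggers cluster teardown, and in cloud mode no instance is left
#' running at terminal state.
#'
#' The shipped `search` protocol stages the query and reference to the
#' cluster, mirrors the reference to all workers peer-to-peer, estimates
#' CPU-hours from the query's k-mer profile against the reference profile,
#' partitions the query so each work unit runs about `target_hours`, runs
#' the toy seed-match worker per partition, and merges results in
#' partition order.
#'
#' @param ctx an [elastiseq_context()].
#' @param config a `pipeline_config` (see [describe_protocol()],
#'   [parse_config()]).
#' @return an object of class `pipeline_run`; inspect with
#'   [describe_pipeline()], plot with `autoplot()`.
#' @export
run_pipeline <- function(ctx, config) {
  ctx$run_counter <- ctx$run_counter + 1L
  id <- sprintf("run-%03d", ctx$run_counter)
  run <- list(
    id = id, config = config, mode = "local", state = "running",
    phases = new_phase_table(), timeseries = list(), results = NULL,
    output_file = NA_character_, cluster = NA_character_,
    t_est = NA_real_, plan = NULL, partition_plan = NULL
  )
  ctx$pipelines[[id]] <- run
  run <- tryCatch(
    pipeline_phases(ctx, run),
    error = function(e) {
      r <- ctx$pipelines[[id]]
      i <- which(r$phases$status == "running")
      if (length(i)) {
        r$phases$status[i] <- "failed"
        r$phases$end[i] <- ctx$cloud$now
      }
      r$state <- "failed"
      r$error <- conditionMessage(e)
      r
    }
  )
  # teardown guarantee: terminal state leaves no running instances
  if (!is.na(run$cluster) && run$cluster != "local" &&
      run$cluster %in% names(ctx$clusters)) {
    terminate_cluster(ctx, run$cluster)
  }
  run <- record_point(ctx, run)
  class(run) <- "pipeline_run"
  ctx$pipelines[[id]] <- run
  run
}

phase_begin <- function(ctx, run, i) {
  run$phases$status[i] <- "running"
  run$phases$start[i] <- ctx$cloud$now
  ctx$pipelines[[run$id]] <- run
  run
}

phase_done <- function(ctx, run, i, status = "complete") {
  run$phases$status[i] <- status
  if (status == "skipped") {
    run$phases$start[i] <- ctx$cloud$now
  }
  run$phases$end[i] <- ctx$cloud$now
  ctx$pipelines[[run$id]] <- run
  record_point(ctx, run)
}

# Count running (non-terminated, booted) instances of the run's cluster by
# inspecting simulator records directly: reporting, not an orchestration
# decision, so it stays off the backend call log.
running_instances_at <- function(ctx, run, t = ctx$cloud$now) {
  if (is.na(run$cluster)) return(0L)
  cl <- ctx$clusters[[run$cluster]]
  if (is.null(cl) || cl$local) return(0L)
  ids <- c(cl$master, cl$workers)
  sum(vapply(ids, function(id) {
    inst <- ctx$cloud$instances[[id]]
    inst$boot_complete <= t && (is.na(inst$termination_time) || inst$termination_time > t)
  }, logical(1)))
}

record_point <- function(ctx, run, t = ctx$cloud$now, jobs = 0L) {
  run$timeseries[[length(run$timeseries) + 1L]] <- tibble(
    time = t, instances = running_instances_at(ctx, run, t),
    running_jobs = as.integer(jobs)
  )
  ctx$pipelines[[run$id]] <- run
  run
}

pipeline_phases <- function(ctx, run) {
  config <- run$config

  # (1) pre-processing: validation and integrity checks
  run <- phase_begin(ctx, run, 1L)
  config <- validate_config(ctx, config)
  run$config <- config
  run$mode <- config$cluster$mode
  if (config$protocol != "search") {
    abort(sprintf(
      "protocol '%s' is registered but only 'search' ships a worker workload",
      config$protocol
    ))
  }
  alphabet <- param_chr(config, "alphabet")
  k <- param_int(config, "k")
  query <- read_fasta(config$inputs$query, alphabet = alphabet)
  reference <- read_fasta(config$inputs$reference, alphabet = alphabet)
  out_dir <- config$output$dir
  if (!nzchar(out_dir)) out_dir <- file.path(tempdir(), run$id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- phase_done(ctx, run, 1L)

  # runtime estimate: query profile against the reference-database profile
  ref_profile <- kmer_profile(reference, k = k)
  weights <- reference_weights(ref_profile)
  model <- runtime_model(
    alpha = param_num(config, "alpha"), beta = param_num(config, "beta"),
    weights = weights, k = k, alphabet = alphabet
  )
  query_profile <- kmer_profile(query, k = k)
  run$t_est <- predict_cpu_hours(model, query_profile)
  policy <- run_policy(config)
  cloud_mode <- run$mode == "cloud"

  # (2) start cluster: protocol floor first, scaling happens in (5)
  if (cloud_mode) {
    run <- phase_begin(ctx, run, 2L)
    floor_plan <- plan_provisioning(config$protocol, 0, policy)
    run$cluster <- run$id
    add_cluster(ctx, run$cluster, config$cluster$credential,
                count = floor_plan$count, type = floor_plan$instance_type)
    run <- phase_done(ctx, run, 2L)
  } else {
    run$cluster <- "local"
    run <- phase_done(ctx, run, 2L, "skipped")
  }

  # (3) upload inputs; mirror the reference staging payload peer-to-peer
  qname <- paste0(run$id, "-query")
  rname <- paste0(run$id, "-reference")
  if (cloud_mode) {
    run <- phase_begin(ctx, run, 3L)
    add_dataset(ctx, "local", qname, config$inputs$query)
    add_dataset(ctx, "local", rname, config$inputs$reference)
    transfer_dataset(ctx, qname, "local", run$cluster)
    transfer_dataset(ctx, rname, "local", run$cluster)
    if (length(ctx$clusters[[run$cluster]]$workers) > 0L) {
      sched <- mirror_staging(
        ctx, run$cluster,
        payload_mb = max(file.size(config$inputs$reference) / 1e6, 1e-6)
      )
      run$staging <- sched
      cloud_advance(ctx$cloud, sched$completion_time)
    }
    run <- phase_done(ctx, run, 3L)
  } else {
    run <- phase_done(ctx, run, 3L, "skipped")
  }

  # (4) partition the query and submit one work unit per partition
  run <- phase_begin(ctx, run, 4L)
  pplan <- plan_partitions(
    nrow(query), run$t_est, param_num(config, "target_hours"),
    mode = param_chr(config, "partition_mode")
  )
  run$partition_plan <- pplan
  parts <- split_fasta(query, pplan, file.path(out_dir, "partitions"))
  for (i in seq_len(nrow(parts))) {
    part_records <- read_fasta(parts$path[i], alphabet = alphabet)
    part_profile <- kmer_profile(part_records, k = k)
    cost <- model$alpha + model$beta * overlap_statistic(part_profile, weights)
    submit_job(
      ctx, run$cluster, work = "toy_search", cost_hours = cost,
      prolog_mb = max(file.size(parts$path[i]) / 1e6, 1e-6),
      epilog_mb = 0.01,
      args = list(partition_path = parts$path[i], reference = reference, k = k)
    )
  }
  run <- phase_done(ctx, run, 4L)

  # (5) monitor: scale out for the parallel stage, run it, terminate idle
  run <- phase_begin(ctx, run, 5L)
  run <- monitor_and_scale(ctx, run, policy)
  run <- phase_done(ctx, run, 5L)

  # merge partition results in partition order on the master
  merged <- dplyr::bind_rows(run$trace$results)
  run$results <- merged
  merged_path <- file.path(out_dir, "merged_results.tsv")
  utils::write.table(merged, merged_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  run$output_file <- merged_path
  oname <- paste0(run$id, "-results")
  producer <- list(
    pipeline_id = run$id, protocol = config$protocol,
    version = config$version, params = config$params
  )

  # (6) download merged outputs from the master
  if (cloud_mode) {
    run <- phase_begin(ctx, run, 6L)
    add_dataset(ctx, run$cluster, oname, merged_path)
    ctx$datasets[[run$cluster]][[oname]]$producer <- producer
    transfer_dataset(ctx, oname, run$cluster, "local")
    run <- phase_done(ctx, run, 6L)
  } else {
    run <- phase_done(ctx, run, 6L, "skipped")
  }

  # (7) post-processing: register the output dataset with provenance
  run <- phase_begin(ctx, run, 7L)
  if (is.null(ctx$datasets[["local"]][[oname]])) {
    add_dataset(ctx, "local", oname, merged_path)
  }
  ctx$datasets[["local"]][[oname]]$producer <- producer
  run$output_dataset <- oname
  run <- phase_done(ctx, run, 7L)

  run$state <- "complete"
  ctx$pipelines[[run$id]] <- run
  run
}

run_policy <- function(config) {
  user_cap <- config$cluster$user_cap
  provision_policy(
    user_cap = if (nzchar(user_cap)) as.integer(user_cap) else NA_integer_,
    target_hours = param_num(config, "target_hours"),
    default_type = config$cluster$instance_type
  )
}

#' Scale for the parallel stage, run it, and terminate idle workers
#'
#' The monitoring phase's scaling behaviour: before the parallel stage the
#' estimate-based provisioning plan is requested and the cluster grown to
#' it with a resize call (cap refusals are logged on the run and execution
#' continues with the available instances); the stage then runs under the
#' queue-slot model; afterwards idle workers are terminated at their next
#' whole-hour uptime boundary while the master persists for the download
#' phase. Polling snapshots are recorded at a fixed virtual interval for
#' the run's execution profile.
#'
#' @param ctx an [elastiseq_context()].
#' @param run a `pipeline_run` in phase 5 (called by [run_pipeline()]).
#' @param policy a [provision_policy()].
#' @param poll_interval virtual hours between monitoring snapshots
#'   (default 0.05).
#' @return the updated run.
#' @export
monitor_and_scale <- function(ctx, run, policy, poll_interval = 0.05) {
  cloud_mode <- run$mode == "cloud"
  if (cloud_mode) {
    desired <- plan_provisioning(run$config$protocol, run$t_est, policy)
    run$plan <- desired
    cl <- ctx$clusters[[run$cluster]]
    current <- 1L + length(cl$workers)
    if (desired$count > current) {
      tryCatch(
        add_instances(ctx, run$cluster, desired$count - current),
        error = function(e) {
          run$scaling_refusal <<- conditionMessage(e)
        }
      )
    }
    run <- record_point(ctx, run)
  }
  trace <- run_queue(ctx, run$cluster)
  run$trace <- trace
  # polling snapshots across the stage, from the event log
  if (nrow(trace$log) > 0L && trace$makespan > 0) {
    for (t in seq(trace$t_start, trace$t_end, by = poll_interval)) {
      execs <- trace$log[trace$log$queue == "exec.q", ]
      run <- record_point(ctx, run, t = t,
                          jobs = sum(execs$start <= t & execs$end > t))
    }
  }
  if (cloud_mode) {
    run <- terminate_idle_workers(ctx, run)
  }
  ctx$pipelines[[run$id]] <- run
  run
}

# Terminate jobless workers on the hourly timer: each is shut down at the
# first instant within `window` of its next whole-hour uptime boundary.
terminate_idle_workers <- function(ctx, run, window = 0.1) {
  cl <- ctx$clusters[[run$cluster]]
  if (length(cl$workers) == 0L) return(run)
  desc <- cloud_describe_instances(ctx$cloud, cl$credential, cl$workers)
  desc <- desc[is.na(desc$termination_time), ]
  if (nrow(desc) == 0L) return(run)
  uptime <- ctx$cloud$now - desc$launch_time
  due_now <- idle_termination_due(uptime, node_busy = FALSE, window = window)
  # time at which each not-yet-due worker reaches its termination window
  boundary <- desc$launch_time + floor(uptime) + 1
  due_at <- ifelse(due_now, ctx$cloud$now, boundary - window)
  for (t in sort(unique(due_at))) {
    cloud_advance(ctx$cloud, t)
    ids <- desc$id[due_at <= t + 1e-12]
    cloud_terminate_instances(ctx$cloud, cl$credential, ids)
    run <- record_point(ctx, run)
    due_at[due_at <= t + 1e-12] <- Inf
  }
  run
}

#' Toy seed-match worker
#'
#' The pluggable stand-in for a real search tool: for each query sequence
#' it counts how many of the query's k-mer windows occur in the reference
#' k-mer set (reference counted over both strands for DNA). Deterministic
#' given its inputs, and per-query independent, so merged results are
#' identical under any partitioning of the query set.
#'
#' @param partition_path path to a partition FASTA (or `records` given
#'   directly).
#' @param reference a `seq_records` tibble of the reference database.
#' @param k word length.
#' @param records optional `seq_records` to use instead of reading
#'   `partition_path`.
#' @return tibble: `query_id`, `n_windows`, `kmer_matches`.
#' @export
toy_search_worker <- function(partition_path = NULL, reference, k = 11L,
                              records = NULL) {
  if (nrow(reference) == 0L) abort("empty reference")
  if (is.null(records)) {
    records <- read_fasta(partition_path, alphabet = reference$alphabet[1])
  }
  ref_words <- names(kmer_profile(reference, k = k)$counts)
  ambiguity <- if (records$alphabet[1] == "dna") "N" else "X"
  res <- lapply(seq_len(nrow(records)), function(i) {
    s <- records$seq[i]
    n <- nchar(s)
    if (n < k) {
      return(tibble(query_id = records$id[i], n_windows = 0L, kmer_matches = 0L))
    }
    w <- substring(s, seq_len(n - k + 1L), seq.int(k, n))
    w <- w[!grepl(ambiguity, w, fixed = TRUE)]
    tibble(
      query_id = records$id[i], n_windows = length(w),
      kmer_matches = sum(w %in% ref_words)
    )
  })
  dplyr::bind_rows(res)
}

#' Pipeline status report
#'
#' @param ctx an [elastiseq_context()].
#' @param id pipeline run id.
#' @return list: `id`, `state`, `phases` (per-phase status tibble),
#'   `timeseries` (instance count and running jobs over virtual time),
#'   `t_est`, `output_dataset`.
#' @export
describe_pipeline <- function(ctx, id) {
  run <- ctx$pipelines[[id]]
  if (is.null(run)) abort(sprintf("unknown pipeline '%s'", id))
  list(
    id = run$id, state = run$state, phases = run$phases,
    timeseries = run_timeseries(run), t_est = run$t_est,
    output_dataset = run$output_dataset %||% NA_character_,
    error = run$error %||% NA_character_
  )
}

#' Execution-profile time series of a run
#'
#' @param run a `pipeline_run`.
#' @return tibble: `time`, `instances`, `running_jobs`, sorted by time.
#' @export
run_timeseries <- function(run) {
  if (length(run$timeseries) == 0L) {
    return(tibble(time = numeric(0), instances = integer(0),
                  running_jobs = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(run$timeseries), .data$time)
}

#' Export a run's execution profile as CSV
#'
#' One row per monitoring snapshot: virtual time, running instance count,
#' running job count — the data behind the classic scale-out/teardown
#' cluster profile plot.
#'
#' @param run a `pipeline_run`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_run_profile <- function(run, path) {
  utils::write.csv(run_timeseries(run), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s [%s mode]: %s\n", x$id, x$mode, x$state))
  s <- x$phases
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %d. %-13s %s\n", s$phase[i], s$name[i], s$status[i]))
  }
  if (!is.na(x$t_est)) cat(sprintf("  estimated CPU-hours: %.3f\n", x$t_est))
  invisible(x)
}
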