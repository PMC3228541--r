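#' Create an orchestration context
#'
#' The top-level session object holding the simulated cloud backend, the
#' cluster table (including the reserved `'local'` cluster, which is both
#' master and worker), the dataset registry, and pipeline runs. All
#' stateful verbs (`add_cluster`, `add_dataset`, `run_pipeline`, ...) take
#' the context as their first argument and mutate it in place.
#'
#' @param seed integer seed driving all simulator randomness (boot jitter,
#'   keypair generation); identical seeds give identical runs.
#' @param local_cpus CPU slots of the local client machine (default 4).
#' @param staging_slots per-host slot limit of the staging.q transfer queue
#'   (concurrent outbound prolog transfers a host will serve; default 2).
#' @param harvesting_slots per-host slot limit of harvesting.q (concurrent
#'   epilog transfers back to the master; default 2).
#' @param ... passed to [cloud_sim()] (`provider_cap`, `boot_latency`,
#'   `boot_jitter`, `bandwidth_mb_s`, `local_link_mb_s`).
#' @return an environment of class `elastiseq_context`.
#' @export
elastiseq_context <- function(seed = 1L, local_cpus = 4L, staging_slots = 2L,
                              harvesting_slots = 2L, ...) {
  ctx <- new.env(parent = emptyenv())
  ctx$seed <- as.integer(seed)
  ctx$cloud <- cloud_sim(seed = seed, ...)
  ctx$local_cpus <- as.integer(local_cpus)
  ctx$staging_slots <- as.integer(staging_slots)
  ctx$harvesting_slots <- as.integer(harvesting_slots)
  ctx$clusters <- list()
  ctx$datasets <- list(local = list())
  ctx$pipelines <- list()
  ctx$run_counter <- 0L
  ctx$protocols <- builtin_protocols()
  ctx$clusters[["local"]] <- list(
    name = "local", credential = NA_character_, local = TRUE,
    master = "local", workers = character(0),
    type = "local", cpus = ctx$local_cpus,
    keypair = make_keypair(ctx$cloud),
    queues = default_queues(ctx, ctx$local_cpus),
    closed = FALSE, created = 0
  )
  class(ctx) <- "elastiseq_context"
  ctx
}

#' @export
print.elastiseq_context <- function(x, ...) {
  cat(sprintf(
    "<elastiseq_context> t=%.3f h, %d cluster(s), %d pipeline run(s)\n",
    x$cloud$now, length(x$clusters), length(x$pipelines)
  ))
  invisible(x)
}

# Opaque random token standing in for the per-cluster SSH keypair; drawn
# from the simulator's private RNG stream so contexts are reproducible.
make_keypair <- function(sim) {
  paste(
    c(0:9, letters[1:6])[ceiling(sim_runif(sim, 32L, 0, 16))],
    collapse = ""
  )
}

default_queues <- function(ctx, cpus) {
  list(
    exec.q = list(name = "exec.q", slots_per_host = as.integer(cpus)),
    staging.q = list(name = "staging.q", slots_per_host = ctx$staging_slots),
    harvesting.q = list(name = "harvesting.q", slots_per_host = ctx$harvesting_slots),
    stagingsub.q = list(name = "stagingsub.q", slots_per_host = ctx$staging_slots,
                        member_hosts = character(0))
  )
}

#' Register a credential with the context
#'
#' @param ctx an [elastiseq_context()].
#' @param name credential name.
#' @param account opaque account id (defaults to `name`).
#' @return `name`, invisibly.
#' @export
add_credential <- function(ctx, name, account = name) {
  cloud_add_credential(ctx$cloud, name, account)
}

get_cluster <- function(ctx, name) {
  cl <- ctx$clusters[[name]]
  if (is.null(cl)) abort(sprintf("unknown cluster '%s'", name))
  cl
}

#' Start a cluster
#'
#' Launches `count` instances in a single backend request. The first
#' instance is designated the master node; the rest register as workers as
#' they boot. Every cluster gets a unique randomly generated keypair and
#' the standard queue set (exec.q with one slot per CPU, plus the
#' staging.q / harvesting.q / stagingsub.q transfer queues).
#'
#' @param ctx an [elastiseq_context()].
#' @param name cluster name (`'local'` is reserved).
#' @param credential registered credential name.
#' @param count total instances including the master (>= 1).
#' @param type instance type name.
#' @return the cluster record, invisibly.
#' @export
add_cluster <- function(ctx, name, credential, count, type = "c1.xlarge") {
  if (name %in% names(ctx$clusters)) {
    abort(sprintf("cluster name '%s' is already in use", name))
  }
  if (count < 1) abort("count must be >= 1")
  ids <- cloud_run_instances(ctx$cloud, credential, type, count)
  cpus <- catalog_type(type)$cpus
  cl <- list(
    name = name, credential = credential, local = FALSE,
    master = ids[1], workers = ids[-1],
    type = type, cpus = cpus,
    keypair = make_keypair(ctx$cloud),
    queues = default_queues(ctx, cpus),
    closed = FALSE, created = ctx$cloud$now
  )
  ctx$clusters[[name]] <- cl
  invisible(cl)
}

#' Resize a cluster
#'
#' Adds worker instances; new workers auto-register with the master as
#' they boot. A request of 0 is a no-op; backend cap refusals propagate.
#'
#' @param ctx an [elastiseq_context()].
#' @param name cluster name.
#' @param count workers to add (>= 0).
#' @return the updated cluster record, invisibly.
#' @export
add_instances <- function(ctx, name, count) {
  cl <- get_cluster(ctx, name)
  if (cl$local) abort("the 'local' cluster cannot be resized")
  if (cl$closed) abort(sprintf("cluster '%s' is terminated", name))
  if (count < 0) abort("count must be >= 0")
  if (count == 0) return(invisible(cl))
  ids <- cloud_run_instances(ctx$cloud, cl$credential, cl$type, count)
  cl$workers <- c(cl$workers, ids)
  ctx$clusters[[name]] <- cl
  invisible(cl)
}

#' Terminate a cluster
#'
#' Terminates every instance of the cluster and closes its record;
#' re-terminating is an idempotent no-op.
#'
#' @param ctx an [elastiseq_context()].
#' @param name cluster name.
#' @return TRUE, invisibly.
#' @export
terminate_cluster <- function(ctx, name) {
  cl <- get_cluster(ctx, name)
  if (cl$local) abort("the 'local' cluster cannot be terminated")
  if (!cl$closed) {
    cloud_terminate_instances(ctx$cloud, cl$credential, c(cl$master, cl$workers))
    cl$closed <- TRUE
    ctx$clusters[[name]] <- cl
  }
  invisible(TRUE)
}

#' Describe a cluster
#'
#' @param ctx an [elastiseq_context()].
#' @param name cluster name.
#' @return list with the cluster record, an instance tibble (role, state,
#'   billed hours) and total CPU count.
#' @export
describe_cluster <- function(ctx, name) {
  cl <- get_cluster(ctx, name)
  if (cl$local) {
    return(list(
      cluster = cl,
      instances = tibble(id = "local", role = "master+worker",
                         state = "running", billed_hours = 0L),
      total_cpus = cl$cpus
    ))
  }
  desc <- cloud_describe_instances(ctx$cloud, cl$credential,
                                   c(cl$master, cl$workers))
  bill <- cloud_billing(ctx$cloud)
  desc$role <- ifelse(desc$id == cl$master, "master", "worker")
  desc$billed_hours <- bill$billed_hours[match(desc$id, bill$id)]
  list(
    cluster = cl,
    instances = desc,
    total_cpus = nrow(desc) * cl$cpus
  )
}

#' Total exec.q slots of a cluster
#'
#' Workers receive work units based on their CPU count: each worker hosts
#' `cpus` exec.q slots (a single-instance cluster runs jobs on its master).
#'
#' @param ctx an [elastiseq_context()].
#' @param name cluster name.
#' @return integer slot count.
#' @export
exec_slots <- function(ctx, name) {
  cl <- get_cluster(ctx, name)
  if (cl$local) return(cl$cpus)
  n_exec_hosts <- max(1L, length(cl$workers))
  n_exec_hosts * cl$cpus
}

#' Submit a job to a cluster queue
#'
#' Queues a work unit with its prolog input transfer (master to the
#' executing worker, scheduled in staging.q) and epilog output transfer
#' (worker back to master, harvesting.q). The job occupies one exec.q slot
#' between prolog completion and epilog start. Jobs run when
#' [run_queue()] is called.
#'
#' @param ctx an [elastiseq_context()].
#' @param cluster cluster name.
#' @param work registered task name (`"noop"` or `"toy_search"`).
#' @param cost_hours CPU-hours the job occupies its exec slot.
#' @param prolog_mb input payload staged to the worker before execution.
#' @param epilog_mb output payload harvested back to the master.
#' @param queue queue name (must exist on the cluster).
#' @param args list of task arguments (for `toy_search`: `partition_path`,
#'   `reference`, `k`).
#' @return the job id, invisibly.
#' @export
submit_job <- function(ctx, cluster, work = "noop", cost_hours = 0,
                       prolog_mb = 0, epilog_mb = 0, queue = "exec.q",
                       args = list()) {
  cl <- get_cluster(ctx, cluster)
  if (!queue %in% names(cl$queues)) {
    abort(sprintf("unknown queue '%s' on cluster '%s'", queue, cluster))
  }
  if (!work %in% c("noop", "toy_search")) {
    abort(sprintf("unknown task '%s'", work))
  }
  cl$pending_jobs <- c(cl$pending_jobs, list(list(
    job_id = sprintf("%s-job-%04d", cluster, length(cl$pending_jobs) + 1L),
    work = work, cost_hours = cost_hours,
    prolog_mb = prolog_mb, epilog_mb = epilog_mb, args = args
  )))
  ctx$clusters[[cluster]] <- cl
  invisible(cl$pending_jobs[[length(cl$pending_jobs)]]$job_id)
}

# Hosts that run exec jobs, with their slot counts and availability times.
exec_hosts <- function(ctx, cl) {
  if (cl$local) {
    return(tibble(host = "local", slots = cl$cpus, avail = ctx$cloud$now))
  }
  hosts <- if (length(cl$workers)) cl$workers else cl$master
  desc <- cloud_describe_instances(ctx$cloud, cl$credential, hosts)
  desc <- desc[is.na(desc$termination_time), ]
  tibble(host = desc$id, slots = cl$cpus, avail = desc$boot_complete)
}

#' Run all pending jobs on a cluster
#'
#' A discrete-event scheduler enforcing queue slot limits at every virtual
#' instant: concurrent prolog transfers out of the master are capped by
#' staging.q slots, concurrent jobs per worker by its exec.q slots (one per
#' CPU), and concurrent epilog transfers by harvesting.q slots. Jobs are
#' assigned to the least-loaded booted worker (ties to the lowest instance
#' id) at prolog start; execution begins when the prolog is complete and a
#' slot on the assigned host frees; transfers move at the intra-cloud link
#' bandwidth. Task functions run at job completion, in job order, so
#' results are deterministic.
#'
#' Advances the virtual clock to the makespan end.
#'
#' @param ctx an [elastiseq_context()].
#' @param cluster cluster name.
#' @return an object of class `job_trace`: list with `log` (tibble of
#'   `job_id`, `queue`, `host`, `start`, `end`), `results` (named list of
#'   task outputs), `t_start`, `t_end`, `makespan`.
#' @export
run_queue <- function(ctx, cluster) {
  cl <- get_cluster(ctx, cluster)
  jobs <- cl$pending_jobs
  cl$pending_jobs <- list()
  ctx$clusters[[cluster]] <- cl
  if (length(jobs) == 0L) {
    return(structure(
      list(log = empty_job_log(), results = list(),
           t_start = ctx$cloud$now, t_end = ctx$cloud$now, makespan = 0),
      class = "job_trace"
    ))
  }
  hosts <- exec_hosts(ctx, cl)
  rate_h <- ctx$cloud$bandwidth_mb_s * 3600 # MB per virtual hour
  staging_slots <- cl$queues$staging.q$slots_per_host
  harvesting_slots <- cl$queues$harvesting.q$slots_per_host

  n <- length(jobs)
  state <- rep("queued", n) # queued->prolog->staged->exec->harvest_wait->epilog->done
  host <- rep(NA_character_, n)
  phase_end <- rep(NA_real_, n)
  prolog_dur <- vapply(jobs, function(j) j$prolog_mb, numeric(1)) / rate_h
  epilog_dur <- vapply(jobs, function(j) j$epilog_mb, numeric(1)) / rate_h
  exec_dur <- vapply(jobs, function(j) j$cost_hours, numeric(1))
  if (cl$local) { # same machine: no network transfers
    prolog_dur[] <- 0
    epilog_dur[] <- 0
  }
  staging_busy <- 0L
  harvest_busy <- 0L
  exec_busy <- stats::setNames(rep(0L, nrow(hosts)), hosts$host)
  assigned_load <- exec_busy
  log <- list()
  t0 <- max(ctx$cloud$now, if (cl$local) 0 else
    cloud_describe_instances(ctx$cloud, cl$credential, cl$master)$boot_complete)
  t <- t0
  eps <- 1e-12

  add_log <- function(job_id, queue, h, start, end) {
    log[[length(log) + 1L]] <<- tibble(
      job_id = job_id, queue = queue, host = h, start = start, end = end
    )
  }

  repeat {
    progressed <- TRUE
    while (progressed) {
      progressed <- FALSE
      # complete phases whose end time has been reached
      for (i in which(!is.na(phase_end) & phase_end <= t + eps)) {
        if (state[i] == "prolog") {
          state[i] <- "staged"; phase_end[i] <- NA_real_
          staging_busy <- staging_busy - 1L
        } else if (state[i] == "exec") {
          state[i] <- "harvest_wait"; phase_end[i] <- NA_real_
          exec_busy[host[i]] <- exec_busy[host[i]] - 1L
        } else if (state[i] == "epilog") {
          state[i] <- "done"; phase_end[i] <- NA_real_
          harvest_busy <- harvest_busy - 1L
          assigned_load[host[i]] <- assigned_load[host[i]] - 1L
        }
        progressed <- TRUE
      }
      # start epilogs (free master harvesting slots permitting)
      for (i in which(state == "harvest_wait")) {
        if (harvest_busy >= harvesting_slots) break
        state[i] <- "epilog"
        harvest_busy <- harvest_busy + 1L
        phase_end[i] <- t + epilog_dur[i]
        add_log(jobs[[i]]$job_id, "harvesting.q",
                if (cl$local) "local" else cl$master, t, phase_end[i])
        progressed <- TRUE
      }
      # start execs on the assigned host when a slot frees (and host booted)
      for (i in which(state == "staged")) {
        h <- host[i]
        if (exec_busy[h] >= hosts$slots[hosts$host == h]) next
        if (hosts$avail[hosts$host == h] > t + eps) next
        state[i] <- "exec"
        exec_busy[h] <- exec_busy[h] + 1L
        phase_end[i] <- t + exec_dur[i]
        add_log(jobs[[i]]$job_id, "exec.q", h, t, phase_end[i])
        progressed <- TRUE
      }
      # start prologs (staging.q slots on master; assign host now)
      for (i in which(state == "queued")) {
        if (staging_busy >= staging_slots) break
        booted <- hosts[hosts$avail <= t + eps, ]
        if (nrow(booted) == 0L) break
        loads <- assigned_load[booted$host]
        h <- booted$host[order(loads, booted$host)][1]
        host[i] <- h
        assigned_load[h] <- assigned_load[h] + 1L
        state[i] <- "prolog"
        staging_busy <- staging_busy + 1L
        phase_end[i] <- t + prolog_dur[i]
        add_log(jobs[[i]]$job_id, "staging.q",
                if (cl$local) "local" else cl$master, t, phase_end[i])
        progressed <- TRUE
      }
    }
    if (all(state == "done")) break
    upcoming <- c(phase_end[!is.na(phase_end)], hosts$avail[hosts$avail > t + eps])
    upcoming <- upcoming[upcoming > t + eps]
    if (length(upcoming) == 0L) {
      abort("job scheduler stalled: no runnable jobs and no future events")
    }
    t <- min(upcoming)
  }

  # run task functions now that the schedule is fixed
  results <- list()
  for (j in jobs) {
    results[[j$job_id]] <- run_task(j)
  }
  cloud_advance(ctx$cloud, t)
  structure(
    list(
      log = dplyr::bind_rows(log), results = results,
      t_start = t0, t_end = t, makespan = t - t0
    ),
    class = "job_trace"
  )
}

empty_job_log <- function() {
  tibble(job_id = character(0), queue = character(0), host = character(0),
         start = numeric(0), end = numeric(0))
}

run_task <- function(job) {
  switch(job$work,
    noop = NULL,
    toy_search = do.call(toy_search_worker, job$args),
    abort(sprintf("unknown task '%s'", job$work))
  )
}

#' @export
print.job_trace <- function(x, ...) {
  cat(sprintf(
    "<job_trace> %d events, makespan %.3f h (t=%.3f..%.3f)\n",
    nrow(x$log), x$makespan, x$t_start, x$t_end
  ))
  invisible(x)
}

#' Mirror the staging directory to every worker
#'
#' Simulates the peer-to-peer staging-directory dissemination: initially
#' only the master holds the payload; as soon as a worker completes its
#' copy it joins stagingsub.q and serves peers itself. Pending recipients
#' (once booted) are matched to the least-loaded eligible source, ties
#' broken by lowest instance id; no source ever serves more than
#' `per_host_limit` concurrent outbound transfers. Transfers are
#' non-preemptive whole-payload copies at the intra-cloud bandwidth
#' (rsync-of-a-directory semantics, no chunking). With uniform links,
#' equal boot times and unit concurrency the source count doubles each
#' round, completing n workers in ceiling(log2(n+1)) rounds.
#'
#' With `p2p = FALSE` only the master ever serves (the baseline the
#' peer-to-peer scheme is measured against).
#'
#' @param ctx an [elastiseq_context()].
#' @param cluster cluster name (must have at least one worker).
#' @param payload_mb staging payload size in MB (> 0).
#' @param per_host_limit max concurrent outbound transfers per source
#'   (default 1).
#' @param p2p workers become sources after completing their copy
#'   (default TRUE).
#' @return an object of class `staging_schedule`: list with `events`
#'   (tibble `source`, `dest`, `mb`, `start`, `end`), `completion_time`,
#'   `t_start`, and `throughput` (tibble `time`, `active`, `mb_s` step
#'   curve). The virtual clock is not advanced; callers decide.
#' @export
mirror_staging <- function(ctx, cluster, payload_mb, per_host_limit = 1L,
                           p2p = TRUE) {
  cl <- get_cluster(ctx, cluster)
  if (cl$local) abort("the 'local' cluster has no workers to mirror to")
  if (length(cl$workers) == 0L) abort("cluster has no workers")
  if (payload_mb <= 0) abort("payload must be > 0")
  desc <- cloud_describe_instances(ctx$cloud, cl$credential,
                                   c(cl$master, cl$workers))
  boot <- stats::setNames(desc$boot_complete, desc$id)
  dur <- payload_mb / (ctx$cloud$bandwidth_mb_s * 3600)
  eps <- 1e-12

  pending <- sort(cl$workers)
  active_end <- stats::setNames(numeric(0), character(0)) # recipient -> end
  active_src <- stats::setNames(character(0), character(0))
  outbound <- stats::setNames(0L, cl$master)
  sources <- cl$master
  events <- list()
  t <- max(ctx$cloud$now, boot[cl$master])
  t0 <- t

  repeat {
    # complete transfers ending now
    done_now <- names(active_end)[active_end <= t + eps]
    for (w in done_now) {
      outbound[active_src[w]] <- outbound[active_src[w]] - 1L
      if (p2p) {
        sources <- c(sources, w)
        outbound[w] <- 0L
      }
      active_end <- active_end[names(active_end) != w]
      active_src <- active_src[names(active_src) != w]
    }
    # start transfers: booted pending recipients x available sources
    repeat {
      ready <- pending[boot[pending] <= t + eps]
      free_src <- sources[outbound[sources] < per_host_limit]
      if (length(ready) == 0L || length(free_src) == 0L) break
      w <- ready[1]
      s <- free_src[order(outbound[free_src], free_src)][1]
      outbound[s] <- outbound[s] + 1L
      start <- t
      end <- t + dur
      events[[length(events) + 1L]] <- tibble(
        source = s, dest = w, mb = payload_mb, start = start, end = end
      )
      active_end[w] <- end
      active_src[w] <- s
      pending <- setdiff(pending, w)
    }
    if (length(pending) == 0L && length(active_end) == 0L) break
    upcoming <- c(active_end, boot[pending][boot[pending] > t + eps])
    upcoming <- upcoming[upcoming > t + eps]
    if (length(upcoming) == 0L) abort("mirroring stalled")
    t <- min(upcoming)
  }

  events <- dplyr::bind_rows(events)
  # update stagingsub.q membership: all workers now hold the payload
  cl$queues$stagingsub.q$member_hosts <- cl$workers
  ctx$clusters[[cluster]] <- cl
  structure(
    list(
      events = events,
      completion_time = max(events$end),
      t_start = t0,
      throughput = throughput_curve(events, ctx$cloud$bandwidth_mb_s)
    ),
    class = "staging_schedule"
  )
}

# Step curve of aggregate transfer throughput: at any instant the
# aggregate rate is (number of active transfers) x per-link bandwidth.
throughput_curve <- function(events, mb_s) {
  if (nrow(events) == 0L) {
    return(tibble(time = numeric(0), active = integer(0), mb_s = numeric(0)))
  }
  times <- sort(unique(c(events$start, events$end)))
  active <- vapply(times, function(t) {
    sum(events$start <= t & events$end > t)
  }, integer(1))
  tibble(time = times, active = active, mb_s = active * mb_s)
}

#' @export
print.staging_schedule <- function(x, ...) {
  cat(sprintf(
    "<staging_schedule> %d transfers, completed at t=%.4f h (peak %d concurrent)\n",
    nrow(x$events), x$completion_time, max(x$throughput$active)
  ))
  invisible(x)
}
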