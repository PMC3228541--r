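#' Create a simulated cloud backend
#'
#' A minimal elastic-cloud provider with a virtual clock (in hours), boot
#' latency with per-instance jitter (instances come online staggered),
#' per-instance ephemeral disks, per-started-hour billing and a per-account
#' instance cap. It exposes exactly the three provider calls the
#' orchestration layer is allowed to use — [cloud_run_instances()],
#' [cloud_terminate_instances()] and [cloud_describe_instances()] — and
#' records every call in an append-only log so that parsimony can be
#' asserted.
#'
#' @param seed integer seed driving boot jitter (and any other backend
#'   randomness); identical seeds give identical boot schedules.
#' @param provider_cap maximum concurrent (non-terminated) instances per
#'   account (default 20).
#' @param boot_latency base boot time in virtual hours (default 0.02).
#' @param boot_jitter uniform jitter added per instance, in hours
#'   (default 0.01).
#' @param bandwidth_mb_s point-to-point bandwidth between running
#'   instances, MB/s (default 40).
#' @param local_link_mb_s bandwidth of the desktop-to-cloud link, MB/s
#'   (default 10; slower than the intra-cloud links).
#' @return an environment of class `cloud_sim`.
#' @export
cloud_sim <- function(seed = 1L, provider_cap = 20L, boot_latency = 0.02,
                      boot_jitter = 0.01, bandwidth_mb_s = 40,
                      local_link_mb_s = 10) {
  sim <- new.env(parent = emptyenv())
  sim$now <- 0
  sim$seed <- as.integer(seed)
  sim$draws <- 0L
  sim$provider_cap <- as.integer(provider_cap)
  sim$boot_latency <- boot_latency
  sim$boot_jitter <- boot_jitter
  sim$bandwidth_mb_s <- bandwidth_mb_s
  sim$local_link_mb_s <- local_link_mb_s
  sim$instances <- list()
  sim$n_created <- 0L
  sim$credentials <- list()
  sim$api_log <- list()
  class(sim) <- "cloud_sim"
  sim
}

#' @export
print.cloud_sim <- function(x, ...) {
  states <- vapply(x$instances, function(i) instance_state(x, i$id), character(1))
  cat(sprintf(
    "<cloud_sim> t=%.3f h, %d instances (%d running), cap %d\n",
    x$now, length(x$instances), sum(states == "running"), x$provider_cap
  ))
  invisible(x)
}

# Deterministic private RNG stream: each draw advances sim$draws so results
# depend only on (seed, draw index), never on the caller's RNG state.
sim_runif <- function(sim, n, min = 0, max = 1) {
  sim$draws <- sim$draws + 1L
  with_seed(sim$seed + sim$draws, stats::runif(n, min, max))
}

log_api <- function(sim, op, n = NA_integer_) {
  sim$api_log[[length(sim$api_log) + 1L]] <- list(op = op, time = sim$now, n = n)
  invisible(NULL)
}

#' Register a cloud-account credential
#'
#' Every backend call carries a credential name: an opaque alias bound to a
#' cloud account so pipelines reference accounts without embedding keys.
#'
#' @param sim a [cloud_sim()].
#' @param name credential name.
#' @param account opaque account identifier (defaults to `name`).
#' @return `name`, invisibly.
#' @export
cloud_add_credential <- function(sim, name, account = name) {
  sim$credentials[[name]] <- list(name = name, account = account)
  invisible(name)
}

check_credential <- function(sim, credential) {
  if (is.null(sim$credentials[[credential]])) {
    abort(sprintf("unknown credential '%s'", credential))
  }
  sim$credentials[[credential]]
}

# Derived state: pending until boot completes, terminated once a
# termination time is set, running in between.
instance_state <- function(sim, id) {
  inst <- sim$instances[[id]]
  if (is.null(inst)) abort(sprintf("unknown instance '%s'", id))
  if (!is.na(inst$termination_time)) return("terminated")
  if (sim$now < inst$boot_complete) return("pending")
  "running"
}

account_active_count <- function(sim, account) {
  sum(vapply(sim$instances, function(i) {
    i$account == account && is.na(i$termination_time)
  }, logical(1)))
}

#' Launch instances (provider call 1 of 3)
#'
#' Creates `count` instances in `pending` state; each transitions to
#' `running` after the configured boot latency plus a per-instance jittered
#' delay, so a batch comes online staggered. A request that would push the
#' account above the provider cap is refused outright.
#'
#' @param sim a [cloud_sim()].
#' @param credential registered credential name.
#' @param type instance type name from the catalog.
#' @param count number of instances (>= 1).
#' @param catalog instance-type catalog.
#' @return character vector of new instance ids.
#' @export
cloud_run_instances <- function(sim, credential, type, count,
                                catalog = instance_catalog()) {
  cred <- check_credential(sim, credential)
  if (count < 1) abort("count must be >= 1")
  trow <- catalog_type(type, catalog)
  log_api(sim, "run_instances", as.integer(count))
  active <- account_active_count(sim, cred$account)
  if (active + count > sim$provider_cap) {
    abort(sprintf(
      "request refused: %d running + %d requested exceeds provider cap %d",
      active, count, sim$provider_cap
    ))
  }
  jitter <- sim_runif(sim, count, 0, sim$boot_jitter)
  ids <- sprintf("i-%04d", sim$n_created + seq_len(count))
  sim$n_created <- sim$n_created + as.integer(count)
  for (j in seq_along(ids)) {
    sim$instances[[ids[j]]] <- list(
      id = ids[j], credential = credential, account = cred$account,
      type = trow$name, cpus = trow$cpus, hourly_cost = trow$hourly_cost,
      launch_time = sim$now,
      boot_complete = sim$now + sim$boot_latency + jitter[j],
      termination_time = NA_real_,
      disk = new.env(parent = emptyenv())
    )
  }
  ids
}

#' Terminate instances (provider call 2 of 3)
#'
#' Sets state to `terminated` at the current virtual time; billing stops at
#' the next whole-hour boundary. Terminating an already-terminated instance
#' is an idempotent no-op.
#'
#' @param sim a [cloud_sim()].
#' @param credential registered credential name.
#' @param ids instance ids.
#' @return tibble of confirmations (`id`, `state`).
#' @export
cloud_terminate_instances <- function(sim, credential, ids) {
  check_credential(sim, credential)
  log_api(sim, "terminate_instances", length(ids))
  for (id in ids) {
    inst <- sim$instances[[id]]
    if (is.null(inst)) abort(sprintf("unknown instance '%s'", id))
    if (is.na(inst$termination_time)) {
      inst$termination_time <- sim$now
      sim$instances[[id]] <- inst
    }
  }
  tibble(id = ids, state = "terminated")
}

#' Describe instances (provider call 3 of 3)
#'
#' Read-only snapshot of instance states at the current virtual time.
#'
#' @param sim a [cloud_sim()].
#' @param credential registered credential name.
#' @param ids optional subset of instance ids.
#' @return tibble: `id`, `type`, `cpus`, `state`, `launch_time`,
#'   `boot_complete`, `termination_time`.
#' @export
cloud_describe_instances <- function(sim, credential, ids = NULL) {
  cred <- check_credential(sim, credential)
  log_api(sim, "describe_instances")
  insts <- sim$instances
  insts <- Filter(function(i) i$account == cred$account, insts)
  if (!is.null(ids)) insts <- insts[names(insts) %in% ids]
  if (length(insts) == 0L) {
    return(tibble(
      id = character(0), type = character(0), cpus = integer(0),
      state = character(0), launch_time = numeric(0),
      boot_complete = numeric(0), termination_time = numeric(0)
    ))
  }
  tibble(
    id = vapply(insts, `[[`, character(1), "id"),
    type = vapply(insts, `[[`, character(1), "type"),
    cpus = vapply(insts, `[[`, integer(1), "cpus"),
    state = unname(vapply(names(insts), function(id) instance_state(sim, id),
                          character(1))),
    launch_time = vapply(insts, `[[`, numeric(1), "launch_time"),
    boot_complete = vapply(insts, `[[`, numeric(1), "boot_complete"),
    termination_time = vapply(insts, `[[`, numeric(1), "termination_time")
  )
}

#' Append-only backend call log
#'
#' Test instrumentation for the three-call parsimony guarantee: every
#' backend invocation is recorded with its operation name and virtual time.
#'
#' @param sim a [cloud_sim()].
#' @return tibble: `op`, `time`, `n`.
#' @export
api_call_log <- function(sim) {
  if (length(sim$api_log) == 0L) {
    return(tibble(op = character(0), time = numeric(0), n = integer(0)))
  }
  tibble(
    op = vapply(sim$api_log, `[[`, character(1), "op"),
    time = vapply(sim$api_log, `[[`, numeric(1), "time"),
    n = vapply(sim$api_log, function(x) as.integer(x$n), integer(1))
  )
}

#' Advance the virtual clock
#'
#' Time only moves forward; advancing past an instance's boot completion
#' makes it `running`.
#'
#' @param sim a [cloud_sim()].
#' @param to target virtual time in hours.
#' @return the new time, invisibly.
#' @export
cloud_advance <- function(sim, to) {
  sim$now <- max(sim$now, to)
  invisible(sim$now)
}

#' Per-instance billing summary
#'
#' Billed hours are `ceiling(uptime)` with a one-hour minimum
#' ([billed_instance_hours()]); running instances are billed up to the
#' current virtual time.
#'
#' @param sim a [cloud_sim()].
#' @return tibble: `id`, `type`, `billed_hours`, `cost`.
#' @export
cloud_billing <- function(sim) {
  insts <- sim$instances
  if (length(insts) == 0L) {
    return(tibble(
      id = character(0), type = character(0),
      billed_hours = integer(0), cost = numeric(0)
    ))
  }
  end <- vapply(insts, function(i) {
    if (is.na(i$termination_time)) sim$now else i$termination_time
  }, numeric(1))
  boot <- vapply(insts, `[[`, numeric(1), "launch_time")
  hours <- billed_instance_hours(boot, pmax(end, boot))
  tibble(
    id = vapply(insts, `[[`, character(1), "id"),
    type = vapply(insts, `[[`, character(1), "type"),
    billed_hours = hours,
    cost = hours * vapply(insts, `[[`, numeric(1), "hourly_cost")
  )
}

#' Ephemeral-disk access
#'
#' Each instance carries a private key/value store standing in for its
#' local ephemeral disk; it becomes inaccessible once the instance is
#' terminated (the local-disk-only storage model — no shared file system).
#'
#' @param sim a [cloud_sim()].
#' @param id instance id.
#' @param key object key.
#' @param bytes payload size to store.
#' @return stored size (`disk_get`), or `key` invisibly (`disk_put`).
#' @export
disk_put <- function(sim, id, key, bytes) {
  if (instance_state(sim, id) == "terminated") {
    abort(sprintf("disk of terminated instance '%s' is inaccessible", id))
  }
  assign(key, bytes, envir = sim$instances[[id]]$disk)
  invisible(key)
}

#' @rdname disk_put
#' @export
disk_get <- function(sim, id, key) {
  if (instance_state(sim, id) == "terminated") {
    abort(sprintf("disk of terminated instance '%s' is inaccessible", id))
  }
  d <- sim$instances[[id]]$disk
  if (!exists(key, envir = d, inherits = FALSE)) {
    abort(sprintf("no object '%s' on instance '%s'", key, id))
  }
  get(key, envir = d, inherits = FALSE)
}
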