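test_that("the first instance is the master and workers fill exec.q slots", {
  ctx <- quiet_context()
  cl <- add_cluster(ctx, "c6", "acct", count = 6)
  expect_equal(length(cl$workers), 5L)
  expect_match(cl$master, "^i-")
  expect_equal(exec_slots(ctx, "c6"), 5L * 8L) # 40 slots on the 8-CPU type
  d <- describe_cluster(ctx, "c6")
  expect_equal(sum(d$instances$role == "master"), 1L)
  expect_equal(d$total_cpus, 48L)

  solo_ctx <- quiet_context()
  solo <- add_cluster(solo_ctx, "solo", "acct", count = 1)
  expect_length(solo$workers, 0L)
  expect_equal(exec_slots(solo_ctx, "solo"), 8L) # master runs jobs alone
})

test_that("every cluster gets a distinct random keypair", {
  ctx <- quiet_context(provider_cap = 50)
  a <- add_cluster(ctx, "a", "acct", count = 2)
  b <- add_cluster(ctx, "b", "acct", count = 2)
  expect_false(identical(a$keypair, b$keypair))
  expect_match(a$keypair, "^[0-9a-f]{32}$")
  expect_error(add_cluster(ctx, "a", "acct", 1), "already in use")
})

test_that("resizing adds auto-registering workers within the caps", {
  ctx <- quiet_context()
  add_cluster(ctx, "grow", "acct", count = 1)
  add_instances(ctx, "grow", 0) # no-op
  expect_length(ctx$clusters$grow$workers, 0L)
  add_instances(ctx, "grow", 15) # the classic 1 -> 16 scale-out
  expect_length(ctx$clusters$grow$workers, 15L)
  expect_equal(describe_cluster(ctx, "grow")$total_cpus, 128L)
  expect_error(add_instances(ctx, "grow", 10), "cap")

  big <- quiet_context(provider_cap = 200)
  add_cluster(big, "huge", "acct", count = 160)
  expect_equal(describe_cluster(big, "huge")$total_cpus, 1280L)
})

test_that("terminating a cluster stops every instance, idempotently", {
  ctx <- quiet_context()
  add_cluster(ctx, "c", "acct", count = 4)
  terminate_cluster(ctx, "c")
  states <- cloud_describe_instances(ctx$cloud, "acct")$state
  expect_true(all(states == "terminated"))
  expect_silent(terminate_cluster(ctx, "c"))
  expect_error(terminate_cluster(ctx, "nope"), "unknown cluster")
  expect_error(add_instances(ctx, "c", 1), "terminated")
})

test_that("submit_job validates queue and task names", {
  ctx <- quiet_context()
  add_cluster(ctx, "c", "acct", count = 2)
  id <- submit_job(ctx, "c", work = "noop", cost_hours = 0.1)
  expect_match(id, "job-0001")
  expect_error(submit_job(ctx, "c", queue = "fast.q"), "unknown queue")
  expect_error(submit_job(ctx, "c", work = "blastx"), "unknown task")
})

test_that("80 unit jobs on 40 slots run as two full waves", {
  ctx <- quiet_context()
  add_cluster(ctx, "c", "acct", count = 6) # 5 workers x 8 CPUs = 40 slots
  for (i in 1:80) submit_job(ctx, "c", cost_hours = 1)
  trace <- run_queue(ctx, "c")
  execs <- trace$log[trace$log$queue == "exec.q", ]
  expect_equal(nrow(execs), 80L)
  expect_equal(max_concurrency(trace$log, "exec.q"), 40L) # all slots busy
  for (h in unique(execs$host)) {
    expect_lte(max_concurrency(trace$log, "exec.q", h), 8L)
  }
  expect_equal(trace$makespan, 2, tolerance = 1e-9)
})

test_that("staging.q slots bound concurrent outbound prolog transfers", {
  ctx <- quiet_context(staging_slots = 2L)
  add_cluster(ctx, "c", "acct", count = 3)
  for (i in 1:10) {
    submit_job(ctx, "c", cost_hours = 0.01, prolog_mb = 7200) # 0.05 h each
  }
  trace <- run_queue(ctx, "c")
  master <- ctx$clusters$c$master
  expect_equal(max_concurrency(trace$log, "staging.q", master), 2L)
  prologs <- trace$log[trace$log$queue == "staging.q", ]
  expect_equal(nrow(prologs), 10L)
  # 10 transfers of 0.05 h through 2 slots need at least 0.25 h
  expect_gte(max(prologs$end) - min(prologs$start), 0.25 - 1e-9)
})

test_that("jobs without transfers start as soon as a slot frees", {
  ctx <- quiet_context()
  add_cluster(ctx, "c", "acct", count = 2)
  submit_job(ctx, "c", cost_hours = 0.5)
  trace <- run_queue(ctx, "c")
  expect_equal(trace$makespan, 0.5, tolerance = 1e-9)
})

test_that("single-worker mirroring takes one transfer at link speed", {
  ctx <- quiet_context()
  add_cluster(ctx, "c", "acct", count = 2)
  sched <- mirror_staging(ctx, "c", payload_mb = 144000) # 1 h at 40 MB/s
  expect_equal(nrow(sched$events), 1L)
  expect_equal(sched$completion_time - sched$t_start, 1, tolerance = 1e-9)
  expect_error(mirror_staging(ctx, "c", 0), "payload")
  solo <- quiet_context()
  add_cluster(solo, "s", "acct", count = 1)
  expect_error(mirror_staging(solo, "s", 10), "no workers")
})

test_that("seven workers complete in exactly three dissemination rounds", {
  ctx <- quiet_context()
  add_cluster(ctx, "c", "acct", count = 8)
  sched <- mirror_staging(ctx, "c", payload_mb = 144000, per_host_limit = 1)
  dur <- 1 # hours per transfer
  expect_equal(sched$completion_time - sched$t_start, 3 * dur, tolerance = 1e-9)
  # sources per round double: 1, 2, 4 transfers
  starts <- sort(unique(round(sched$events$start - sched$t_start, 9)))
  counts <- vapply(starts, function(s) {
    sum(abs(sched$events$start - sched$t_start - s) < 1e-9)
  }, integer(1))
  expect_equal(counts, c(1L, 2L, 4L))
})

test_that("dissemination rounds follow ceiling(log2(n+1)) generally", {
  for (n_workers in c(1, 2, 3, 4, 6, 12, 15)) {
    ctx <- quiet_context(provider_cap = 20)
    add_cluster(ctx, "c", "acct", count = n_workers + 1)
    sched <- mirror_staging(ctx, "c", payload_mb = 144000, per_host_limit = 1)
    expect_equal(sched$completion_time - sched$t_start, oracle_rounds(n_workers),
                 tolerance = 1e-9, info = sprintf("n=%d", n_workers))
  }
})

test_that("mirroring is complete and never re-sends", {
  ctx <- quiet_context(provider_cap = 40)
  cl <- add_cluster(ctx, "c", "acct", count = 33)
  sched <- mirror_staging(ctx, "c", payload_mb = 100)
  expect_setequal(sched$events$dest, cl$workers)
  expect_equal(nrow(sched$events), 32L) # one receive per worker, no extras
  expect_equal(sum(sched$events$mb), 32 * 100)
  # no source exceeds the per-host outbound limit
  for (s in unique(sched$events$source)) {
    ev <- sched$events[sched$events$source == s, ]
    overlap <- vapply(ev$start, function(t) {
      sum(ev$start <= t + 1e-12 & ev$end > t + 1e-12)
    }, integer(1))
    expect_lte(max(overlap), 1L)
  }
})

test_that("peer-to-peer mirroring beats the master-only baseline for n >= 4", {
  for (n_workers in c(4, 10, 100)) {
    ctx <- quiet_context(provider_cap = 200)
    add_cluster(ctx, "c", "acct", count = n_workers + 1)
    p2p <- mirror_staging(ctx, "c", payload_mb = 3600, per_host_limit = 1)
    base <- mirror_staging(ctx, "c", payload_mb = 3600, per_host_limit = 1,
                           p2p = FALSE)
    t_p2p <- p2p$completion_time - p2p$t_start
    t_base <- base$completion_time - base$t_start
    expect_lt(t_p2p, t_base)
    # doubling sources at least halve the makespan once two rounds of
    # doubling fit (ceil(log2(n+1)) <= n/2 from n = 8 up)
    if (n_workers >= 8) expect_lte(t_p2p, t_base / 2 * 1.01)
    # the p2p aggregate throughput peak strictly exceeds the baseline's
    expect_gt(max(p2p$throughput$mb_s), max(base$throughput$mb_s))
    # and matches the dissemination oracle exactly under uniform links
    expect_equal(t_p2p, oracle_rounds(n_workers) * 3600 / (40 * 3600),
                 tolerance = 1e-9)
  }
})

test_that("staggered boots delay a worker's first copy, not the schedule's validity", {
  ctx <- elastiseq_context(seed = 3, provider_cap = 50,
                           boot_latency = 0.05, boot_jitter = 0.2)
  add_credential(ctx, "acct")
  cl <- add_cluster(ctx, "c", "acct", count = 12)
  sched <- mirror_staging(ctx, "c", payload_mb = 1440) # 0.01 h per copy
  desc <- cloud_describe_instances(ctx$cloud, "acct")
  boots <- stats::setNames(desc$boot_complete, desc$id)
  # nobody receives before they boot, and every worker is served
  expect_true(all(sched$events$start >= boots[sched$events$dest] - 1e-12))
  expect_setequal(sched$events$dest, cl$workers)
})
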