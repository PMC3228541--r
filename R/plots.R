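#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_segment labs
#'   theme_minimal sec_axis scale_y_continuous
#' @export
ggplot2::autoplot

#' Plot a staging-dissemination schedule
#'
#' A transfer Gantt chart: one horizontal segment per transfer, master
#' transfers distinguished from worker-to-worker (peer) transfers by
#' colour — the visual signature of the peer-to-peer scheme is the
#' doubling of concurrent segments each round.
#'
#' @param object a `staging_schedule` from [mirror_staging()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.staging_schedule <- function(object, ...) {
  ev <- object$events
  master <- ev$source[1] # at the start only the master can serve
  ev$role <- ifelse(ev$source == master, "from master", "peer-to-peer")
  ggplot(ev, aes(x = .data$start, xend = .data$end,
                 y = .data$dest, yend = .data$dest, colour = .data$role)) +
    geom_segment(linewidth = 2) +
    labs(x = "virtual time (h)", y = "recipient instance",
         colour = NULL, title = "Staging-directory dissemination") +
    theme_minimal()
}

#' Plot the aggregate staging throughput curve
#'
#' Step curve of the aggregate transfer rate over virtual time (number of
#' concurrent transfers times the per-link bandwidth): peer-to-peer
#' mirroring ramps the aggregate rate up as completed workers join in as
#' sources, where a master-only mirror stays flat at one link's worth.
#'
#' @param schedule a `staging_schedule`.
#' @return a ggplot.
#' @export
plot_throughput <- function(schedule) {
  tp <- schedule$throughput
  ggplot(tp, aes(x = .data$time, y = .data$mb_s)) +
    geom_step() +
    labs(x = "virtual time (h)", y = "aggregate throughput (MB/s)",
         title = "Aggregate staging throughput") +
    theme_minimal()
}

#' Plot a pipeline run's execution profile
#'
#' The classic elastic-cluster profile: running instance count (step
#' line) and concurrently running jobs over virtual time, showing the
#' scale-out before the parallel stage, the busy plateau, idle-worker
#' termination at hourly boundaries and final teardown to zero.
#'
#' @param object a `pipeline_run`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pipeline_run <- function(object, ...) {
  ts <- run_timeseries(object)
  ts_long <- dplyr::bind_rows(
    tibble(time = ts$time, value = ts$instances, series = "running instances"),
    tibble(time = ts$time, value = ts$running_jobs, series = "running jobs")
  )
  ggplot(ts_long, aes(x = .data$time, y = .data$value, colour = .data$series)) +
    geom_step() +
    labs(x = "virtual time (h)", y = "count", colour = NULL,
         title = sprintf("Execution profile of %s (%s mode)",
                         object$id, object$mode)) +
    theme_minimal()
}
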