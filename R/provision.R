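#' Default instance-type catalog
#'
#' The instance types the policies reference: the 8-CPU `c1.xlarge`
#' (7.5 GB RAM) general search workhorse, the high-memory `m2.xlarge`
#' (17.1 GB RAM) used for short-read assembly, and the 4-CPU `medium`
#' (8 GB RAM) found on academic clouds. The `c1.xlarge` hourly cost of
#' 0.675 currency-units reproduces ~108/hour for a 160-instance cluster;
#' it is used for cost reporting only.
#'
#' @return a tibble with columns `name`, `cpus`, `ram_gb`, `hourly_cost`.
#' @export
instance_catalog <- function() {
  tibble(
    name = c("c1.xlarge", "m2.xlarge", "medium"),
    cpus = c(8L, 2L, 4L),
    ram_gb = c(7.5, 17.1, 8),
    hourly_cost = c(0.675, 0.45, 0)
  )
}

catalog_type <- function(name, catalog = instance_catalog()) {
  row <- catalog[catalog$name == name, ]
  if (nrow(row) == 0L) abort(sprintf("unknown instance type '%s'", name))
  row
}

PROTOCOL_IDS <- c("search", "microbe", "sixteen_s", "metagenomics")

#' Provisioning policy
#'
#' Bundles the sizing knobs: the protocol floor (default 5 instances — with
#' the default 8-CPU type that is the 40-CPU floor backing parallel search
#' steps), the provider's per-account cap (default 20), an optional
#' user-configured cap, the preferred per-partition runtime R and the
#' default instance type.
#'
#' @param min_instances floor on the cluster size for search-backed
#'   protocols (default 5).
#' @param provider_cap provider per-account instance limit (default 20).
#' @param user_cap optional user instance limit (`NA` = unset). An explicit
#'   user cap is never exceeded, even by the floor.
#' @param target_hours preferred hours per partition, R (default 2).
#' @param default_type instance type name from [instance_catalog()].
#' @return list of class `provision_policy`.
#' @export
provision_policy <- function(min_instances = 5L, provider_cap = 20L,
                             user_cap = NA_integer_, target_hours = 2,
                             default_type = "c1.xlarge") {
  if (min_instances < 1 || provider_cap < 1) abort("instance counts must be >= 1")
  if (!is.na(user_cap) && user_cap < 1) abort("user_cap must be >= 1 when set")
  structure(
    list(
      min_instances = as.integer(min_instances),
      provider_cap = as.integer(provider_cap),
      user_cap = as.integer(user_cap),
      target_hours = target_hours,
      default_type = default_type
    ),
    class = "provision_policy"
  )
}

#' Choose instance type and count for a protocol run
#'
#' Applies the provisioning hierarchy in order: (1) hard-coded assumptions
#' about resource use — a `microbe` run tagged `illumina-assembly` gets a
#' single high-memory `m2.xlarge`, and search-backed protocols never start
#' below the policy floor; (2) the provider's account cap; (3) the user's
#' configured cap. Between floor and caps, the count targets a wall-clock
#' of about R hours: `count = ceiling(t_est / (target_hours * cpus))`, i.e.
#' each CPU processes roughly one R-hour partition.
#'
#' @param protocol one of `"search"`, `"microbe"`, `"sixteen_s"`,
#'   `"metagenomics"`.
#' @param t_est estimated total CPU-hours (>= 0).
#' @param policy a [provision_policy()].
#' @param input_traits character tags describing the input (e.g.
#'   `"illumina-assembly"`).
#' @param catalog instance-type catalog.
#' @return an object of class `provision_plan`: one-row tibble with
#'   `instance_type`, `cpus`, `count`, `total_cpus`, `rationale`
#'   (`hardcoded`, `estimated` or `capped`).
#' @export
plan_provisioning <- function(protocol, t_est, policy = provision_policy(),
                              input_traits = character(),
                              catalog = instance_catalog()) {
  if (!protocol %in% PROTOCOL_IDS) {
    abort(sprintf(
      "unknown protocol '%s' (known: %s)", protocol,
      paste(PROTOCOL_IDS, collapse = ", ")
    ))
  }
  if (nrow(catalog) == 0L) abort("instance catalog is empty")
  if (t_est < 0) abort("t_est must be >= 0")

  if (protocol == "microbe" && "illumina-assembly" %in% input_traits) {
    type <- catalog_type("m2.xlarge", catalog)
    count <- 1L
    rationale <- "hardcoded"
  } else {
    type <- catalog_type(policy$default_type, catalog)
    estimated <- as.integer(ceiling(t_est / (policy$target_hours * type$cpus)))
    count <- max(policy$min_instances, estimated)
    rationale <- if (estimated > policy$min_instances) "estimated" else "hardcoded"
  }
  cap <- min(policy$provider_cap, policy$user_cap, na.rm = TRUE)
  if (count > cap) {
    count <- as.integer(cap)
    rationale <- "capped"
  }
  plan <- tibble(
    instance_type = type$name, cpus = type$cpus, count = count,
    total_cpus = count * type$cpus, rationale = rationale
  )
  class(plan) <- c("provision_plan", class(plan))
  plan
}

#' Is an idle node due for termination?
#'
#' Idle instances are terminated on an hourly timer: billing accrues in
#' whole instance-hours, so a jobless node is shut down just before its
#' next whole-hour uptime boundary. A node is due when it is idle and
#' within `window` hours of that boundary.
#'
#' @param node_uptime uptime in hours (vectorised).
#' @param node_busy logical; is the node running jobs (vectorised).
#' @param window hours before the boundary in which termination fires
#'   (default 0.1).
#' @return logical vector.
#' @export
idle_termination_due <- function(node_uptime, node_busy, window = 0.1) {
  if (any(node_uptime < 0)) abort("uptime must be >= 0")
  gap <- 1 - (node_uptime %% 1)
  !node_busy & gap <= window + 1e-9
}

#' Billed instance-hours for one instance
#'
#' Cloud billing is per started hour: `ceiling(uptime)` with a minimum of
#' one hour.
#'
#' @param boot boot time in virtual hours.
#' @param terminate termination time in virtual hours (>= boot).
#' @return integer hours (vectorised).
#' @export
billed_instance_hours <- function(boot, terminate) {
  if (any(terminate < boot)) abort("terminate must be >= boot")
  pmax(1L, as.integer(ceiling(terminate - boot)))
}
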