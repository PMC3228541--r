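make_files <- function(dir, sizes) {
  paths <- file.path(dir, sprintf("f%d.dat", seq_along(sizes)))
  for (i in seq_along(sizes)) {
    writeLines(strrep("x", sizes[i] - 1L), paths[i]) # -1 for the newline
  }
  paths
}

test_that("dataset registration records bytes and rejects duplicates", {
  ctx <- quiet_context()
  dir <- withr::local_tempdir()
  paths <- make_files(dir, c(100L, 250L, 50L))
  ds <- add_dataset(ctx, "local", "reads", paths)
  expect_equal(ds$bytes, 400)
  expect_equal(unname(ds$file_bytes), c(100, 250, 50))
  expect_error(add_dataset(ctx, "local", "reads", paths[1]), "already registered")
  expect_error(add_dataset(ctx, "local", "ghost", file.path(dir, "nope")),
               "missing")
  expect_error(add_dataset(ctx, "local", "none", character(0)), "at least one")
})

test_that("dataset transfer is idempotent and re-sends only changed files", {
  ctx <- quiet_context()
  dir <- withr::local_tempdir()
  paths <- make_files(dir, c(1000L, 2000L))
  add_cluster(ctx, "c", "acct", count = 2)
  add_dataset(ctx, "local", "d", paths)

  first <- transfer_dataset(ctx, "d", "local", "c")
  expect_equal(sum(first$bytes_moved), 3000)
  second <- transfer_dataset(ctx, "d", "local", "c")
  expect_equal(sum(second$bytes_moved), 0)
  expect_true(all(second$skipped))

  writeLines(strrep("y", 1999L), paths[2]) # touch one file
  third <- transfer_dataset(ctx, "d", "local", "c")
  expect_equal(third$bytes_moved, c(0, 2000))
  expect_error(transfer_dataset(ctx, "ghost", "local", "c"), "no dataset")
})

test_that("transfer time follows the simulated link bandwidth", {
  ctx <- quiet_context(local_link_mb_s = 10)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "big.dat")
  writeBin(raw(36000), path) # 36 kB at 10 MB/s -> 1e-6 h
  add_cluster(ctx, "c", "acct", count = 2)
  add_dataset(ctx, "local", "big", path)
  t0 <- ctx$cloud$now
  rep1 <- transfer_dataset(ctx, "big", "local", "c")
  expect_equal(ctx$cloud$now - t0, attr(rep1, "hours"))
  expect_equal(attr(rep1, "hours"), 36000 / 1e6 / (10 * 3600))
})

test_that("dataset descriptions expose provenance only for pipeline outputs", {
  ctx <- quiet_context()
  dir <- withr::local_tempdir()
  path <- make_files(dir, 64L)
  add_dataset(ctx, "local", "fresh", path, tags = list(kind = "reads"))
  meta <- describe_dataset(ctx, "fresh")
  expect_null(meta$producer)
  expect_equal(meta$bytes, 64)
  expect_equal(meta$tags$kind, "reads")
  expect_error(describe_dataset(ctx, "nope"), "no dataset")
})

test_that("reference mirroring copies once and self-heals on corruption", {
  src_dir <- withr::local_tempdir()
  store <- withr::local_tempdir()
  src <- file.path(src_dir, "ref.fasta")
  write_fasta(generate_synthetic(5, 50, 60, seed = 8), src)

  first <- mirror_reference_once("ref.fasta", src, store)
  expect_equal(first$bytes_moved, file.size(src))
  second <- mirror_reference_once("ref.fasta", src, store)
  expect_equal(second$bytes_moved, 0)
  expect_equal(readLines(second$path), readLines(src))

  writeLines("corrupted", first$path)
  healed <- mirror_reference_once("ref.fasta", src, store)
  expect_gt(healed$bytes_moved, 0)
  expect_equal(readLines(healed$path), readLines(src))
  expect_error(mirror_reference_once("x", file.path(src_dir, "none"), store),
               "unresolvable")
})

test_that("the search template carries the 2-hour partition target", {
  ctx <- quiet_context()
  tmpl <- describe_protocol(ctx, "search")
  expect_equal(tmpl$params$target_hours, "2")
  expect_equal(tmpl$params$k, "11")
  expect_setequal(names(tmpl$inputs), c("query", "reference"))
  expect_error(describe_protocol(ctx, "annotate"), "unknown protocol")
})

test_that("configurations round-trip through the file dialect", {
  ctx <- quiet_context()
  for (id in c("search", "microbe", "sixteen_s", "metagenomics")) {
    tmpl <- describe_protocol(ctx, id)
    path <- withr::local_tempfile(fileext = ".conf")
    write_config(tmpl, path)
    expect_equal(parse_config(path), tmpl, info = id)
  }
})

test_that("the config dialect tolerates comments and rejects junk", {
  cfg <- parse_config(text = c(
    "# pipeline spec",
    "[pipeline]",
    "protocol=search",
    "[params]",
    "k = 7   # small words",
    "[cluster]",
    "mode=cloud"
  ))
  expect_equal(cfg$params$k, "7")
  expect_equal(cfg$cluster$mode, "cloud")
  expect_error(parse_config(text = c("[warp]", "x=1")), "unknown config section")
  expect_error(parse_config(text = c("x=1")), "before any")
  expect_error(parse_config(text = c("[pipeline]", "protocol=search", "junk line")),
               "unparseable")
})

test_that("validation rejects unknown keys and missing inputs", {
  ctx <- quiet_context()
  cfg <- describe_protocol(ctx, "search")
  cfg$inputs$query <- "q.fa"
  cfg$inputs$reference <- "r.fa"
  ok <- validate_config(ctx, cfg)
  expect_equal(ok$params$target_hours, "2") # defaults merged in

  bad_param <- cfg
  bad_param$params$evalue <- "1e-5"
  expect_error(validate_config(ctx, bad_param), "unknown parameter")

  bad_slot <- cfg
  bad_slot$inputs$database <- "db.fa"
  expect_error(validate_config(ctx, bad_slot), "unknown input slot")

  bad_mode <- cfg
  bad_mode$cluster$mode <- "grid"
  expect_error(validate_config(ctx, bad_mode), "mode")

  noquery <- cfg
  noquery$inputs$query <- ""
  expect_error(validate_config(ctx, noquery), "missing required input")
})
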