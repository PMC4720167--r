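entries_tbl <- function(mz, rt_start, rt_end, ...) {
  tibble::tibble(mz = mz, rt_start = rt_start, rt_end = rt_end, ...)
}

key_cols <- function(x) {
  d <- as.data.frame(x)[, c("mz", "rt_start", "rt_end", "n_members")]
  rownames(d) <- NULL
  d
}

test_that("parsing a tabular export maps columns through the dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("m/z,RT [min],Charge,Intensity",
               "500.2500,35.20,2,12000"), path)
  out <- parse_exclusion_export(path, rt_pad = 2.0)
  expect_equal(nrow(out), 1)
  expect_equal(out$mz, 500.25)
  expect_equal(out$rt_start, 33.2)
  expect_equal(out$rt_end, 37.2)
  expect_equal(out$charge, 2L)
  expect_equal(out$intensity, 12000)

  writeLines("m/z,RT [min],Charge,Intensity", path)
  expect_equal(nrow(parse_exclusion_export(path)), 0)

  writeLines(c("m/z,RT [min]", "500.1,30", "abc,31"), path)
  expect_error(parse_exclusion_export(path), "row 2")

  writeLines(c("mass,RT [min]", "500.1,30"), path)
  expect_error(parse_exclusion_export(path), "m/z")
})

test_that("cluster_merge reproduces the worked merge cases", {
  out <- cluster_merge(entries_tbl(c(500.0000, 500.0040), c(30, 33),
                                   c(34, 37)), ppm_tolerance = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$mz, 500.0020)
  expect_equal(out$rt_start, 30)
  expect_equal(out$rt_end, 37)

  out <- cluster_merge(entries_tbl(c(500.0000, 500.0100), c(30, 33),
                                   c(34, 37)), ppm_tolerance = 10)
  expect_equal(nrow(out), 2)  # 20 ppm apart

  out <- cluster_merge(entries_tbl(c(500, 500), c(10, 20), c(12, 22)),
                       ppm_tolerance = 10, rt_gap = 0)
  expect_equal(nrow(out), 2)  # disjoint RT
})

test_that("cluster_merge matches the pairwise fixpoint oracle and is
           canonical", {
  set.seed(101)
  for (i in 1:60) {
    d <- random_entries(max_clusters = sample(3:15, 1))
    gap <- sample(c(0, 0.5), 1)
    got <- cluster_merge(d, ppm_tolerance = 10, rt_gap = gap)
    want <- oracle_cluster_merge(d, ppm = 10, rt_gap = gap)
    expect_equal(key_cols(got), want, tolerance = 1e-9)
    # idempotence
    again <- cluster_merge(got, ppm_tolerance = 10, rt_gap = gap)
    expect_equal(key_cols(again), key_cols(got), tolerance = 1e-12)
    # permutation invariance
    perm <- d[sample(nrow(d)), ]
    expect_equal(key_cols(cluster_merge(perm, ppm_tolerance = 10,
                                        rt_gap = gap)),
                 key_cols(got), tolerance = 1e-12)
    # post-condition audit: no remaining pair is mergeable
    expect_equal(nrow(oracle_cluster_merge(key_cols(got), ppm = 10,
                                           rt_gap = gap)),
                 nrow(got))
  }
})

windows <- function(x) {
  d <- as.data.frame(x)[, c("mz", "rt_start", "rt_end")]
  rownames(d) <- NULL
  d
}

test_that("merge_lists is an identity for empty input and idempotent", {
  a <- exclusion_list(entries_tbl(500.0000, 30, 34), ppm_tolerance = 10)
  empty <- exclusion_list(ppm_tolerance = 10)
  expect_equal(key_cols(merge_lists(a, empty)), key_cols(a))
  # self-merge leaves the precursor windows unchanged
  expect_equal(windows(merge_lists(a, a)), windows(a))

  b <- exclusion_list(entries_tbl(c(500.0030, 600.0000), c(32, 50),
                                  c(36, 54)), ppm_tolerance = 10)
  m <- merge_lists(a, b)
  expect_equal(m$mz, c(500.0015, 600.0000))
  expect_equal(m$rt_start, c(30, 50))
  expect_equal(m$rt_end, c(36, 54))
})

test_that("merge_lists keeps the stricter tolerance and concatenates
           provenance", {
  a <- exclusion_list(entries_tbl(500, 30, 34), ppm_tolerance = 10,
                      provenance = "run1")
  b <- exclusion_list(entries_tbl(800, 10, 14), ppm_tolerance = 5,
                      provenance = "run2")
  m <- merge_lists(a, b)
  expect_equal(attr(m, "ppm_tolerance"), 5)
  expect_setequal(attr(m, "provenance"), c("run1", "run2"))
})

test_that("merge_lists is associative up to canonical form", {
  set.seed(77)
  for (i in 1:20) {
    parts <- lapply(1:3, function(j) {
      exclusion_list(random_entries(max_clusters = 6), ppm_tolerance = 10)
    })
    left <- merge_lists(merge_lists(parts[[1]], parts[[2]]), parts[[3]])
    right <- merge_lists(parts[[1]], merge_lists(parts[[2]], parts[[3]]))
    expect_equal(key_cols(left), key_cols(right), tolerance = 1e-9)
  }
})

test_that("cap_list keeps the highest-intensity entries and validates its
           policy", {
  d <- exclusion_list(entries_tbl(c(500, 600, 700), c(1, 2, 3), c(4, 5, 6),
                                  intensity = c(10, 20, 30)))
  expect_equal(nrow(cap_list(d, 2000)), 3)
  capped <- cap_list(d, 2)
  expect_setequal(capped$intensity, c(30, 20))
  expect_equal(nrow(cap_list(d, 0)), 0)
  expect_error(cap_list(d, 2, policy = "alphabetical"), "unknown cap policy")
  # entries without intensity rank below any with intensity
  e <- exclusion_list(entries_tbl(c(500, 600), c(1, 2), c(4, 5),
                                  intensity = c(NA, 5)))
  expect_equal(cap_list(e, 1)$mz, 600)
})

test_that("instrument CSV export applies the stated rounding and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  x <- exclusion_list(entries_tbl(500.25004, 30.123, 34.567))
  export_instrument_table(x, path)
  lines <- readLines(path)
  expect_equal(lines[1], "Mass,Start (min),End (min)")
  expect_equal(lines[2], "500.2500,30.12,34.57")

  export_instrument_table(exclusion_list(), path)
  expect_equal(readLines(path), "Mass,Start (min),End (min)")

  set.seed(8)
  for (i in 1:20) {
    d <- random_entries(max_clusters = 8)
    lst <- exclusion_list(d)
    export_instrument_table(lst, path)
    back <- parse_instrument_table(path)
    want <- dplyr::arrange(
      tibble::tibble(mz = round(lst$mz, 4),
                     rt_start = round(lst$rt_start, 2),
                     rt_end = round(lst$rt_end, 2)),
      mz, rt_start, rt_end)
    got <- dplyr::arrange(windows(back), mz, rt_start, rt_end)
    expect_equal(got, as.data.frame(want), tolerance = 1e-9)
  }
})

test_that("the rich TSV format round-trips entries and metadata exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  x <- exclusion_list(
    entries_tbl(c(500.1234567, 900.87654), c(10.5, 50.25), c(14.5, 54.25),
                charge = c(2L, NA), intensity = c(1e5, NA),
                source_run = c("iter1", NA)),
    ppm_tolerance = 7.5, rt_pad = 1.5, provenance = c("iter1", "iter2"))
  write_exclusion_tsv(x, path)
  back <- read_exclusion_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(x), tolerance = 1e-9)
  expect_equal(attr(back, "ppm_tolerance"), 7.5)
  expect_equal(attr(back, "rt_pad"), 1.5)
  expect_equal(attr(back, "provenance"), c("iter1", "iter2"))
})

test_that("entry validation catches malformed windows", {
  expect_error(exclusion_list(entries_tbl(-1, 0, 1)), "positive")
  expect_error(exclusion_list(entries_tbl(500, 5, 1)), "rt_start")
})
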