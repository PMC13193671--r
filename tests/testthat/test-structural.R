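make_39_dataset <- function(n_absent = 0, n_empty = 0, seed = 1) {
  # populate all 39 manifest tables with one row, then drop/empty a random
  # subset (never person, so profiles stay runnable)
  m <- default_manifest()
  nms <- manifest_table_names(m)
  tabs <- lapply(m$tables, function(tb) {
    cols <- vapply(tb$columns, `[[`, "", "name")
    as.data.frame(stats::setNames(as.list(rep("1", length(cols))), cols),
                  stringsAsFactors = FALSE)
  })
  names(tabs) <- nms
  set.seed(seed)
  pick <- sample(setdiff(nms, "person"), n_absent + n_empty)
  absent <- pick[seq_len(n_absent)]
  empty <- setdiff(pick, absent)
  for (nm in empty) tabs[[nm]] <- tabs[[nm]][0, , drop = FALSE]
  tabs <- tabs[setdiff(nms, absent)]
  list(dir = write_tiny(tabs), absent = absent, empty = empty)
}

test_that("tables classify as available, empty or not available", {
  fx <- make_39_dataset(n_absent = 1, n_empty = 1, seed = 42)
  h <- open_dataset(fx$dir)
  expect_identical(classify_table(h, fx$absent), "not_available")
  expect_identical(classify_table(h, fx$empty), "empty")
  expect_identical(classify_table(h, "person"), "available")
})

test_that("availability percentages reproduce known fractions with half-up rounding", {
  fx <- make_39_dataset(n_absent = 5, n_empty = 7, seed = 7)
  h <- open_dataset(fx$dir)
  s <- structural_report(h)
  expect_identical(s$n_tables, 39L)
  expect_identical(s$n_not_available, 5L)
  expect_identical(s$n_empty, 7L)
  expect_equal(s$pct_not_available, 12.8)  # 5/39
  expect_equal(s$pct_empty, 17.9)          # 7/39
  expect_equal(s$n_available + s$n_empty + s$n_not_available, s$n_tables)
  expect_equal(s$total_rows, sum(s$per_table$rows[s$per_table$status == "available"]))

  full <- make_39_dataset(0, 0)
  sf <- structural_report(open_dataset(full$dir))
  expect_equal(sf$pct_empty, 0.0)
  expect_equal(sf$pct_not_available, 0.0)
})

test_that("status partition holds under random dropping and emptying", {
  for (i in 1:15) {
    na <- sample(0:6, 1); ne <- sample(0:6, 1)
    fx <- make_39_dataset(na, ne, seed = 100 + i)
    s <- structural_report(open_dataset(fx$dir))
    expect_identical(s$n_available + s$n_empty + s$n_not_available, 39L)
    expect_identical(s$n_not_available, length(fx$absent))
    expect_identical(s$n_empty, length(fx$empty))
    expect_setequal(s$per_table$table[s$per_table$status == "not_available"], fx$absent)
  }
})

test_that("volume fractions follow byte sizes and order descending", {
  d <- tempfile("vol_"); dir.create(d)
  # three tables with byte sizes in ratio 1:2:7 beyond a common header
  hdr <- "x\n"
  writeLines(c("x", strrep("a", 99)), file.path(d, "person.csv"), sep = "\n")
  writeLines(c("x", strrep("b", 199)), file.path(d, "observation.csv"), sep = "\n")
  writeLines(c("x", strrep("c", 699)), file.path(d, "measurement.csv"), sep = "\n")
  m <- schema_manifest(list(table_spec("person", list(column_spec("x"))),
                            table_spec("observation", list(column_spec("x"))),
                            table_spec("measurement", list(column_spec("x")))))
  h <- open_dataset(d)
  vp <- volume_profile(h, m)
  expect_identical(vp$table[1], "measurement")  # largest share first
  expect_equal(sum(vp$fraction), 1, tolerance = 1e-9)
  b <- vp$bytes - min(vp$bytes) * 0  # raw sizes include identical headers
  expect_equal(vp$fraction, b / sum(b))

  one <- volume_profile(h, schema_manifest(list(table_spec("person", list(column_spec("x"))))))
  expect_equal(one$fraction, 1.0)
})

test_that("interpretation notes mark derived-empty and missing free-text tables", {
  fx <- make_39_dataset(0, 0)
  # empty the derived dose_era and a non-derived table; drop the note table
  unlink(file.path(fx$dir, "note.csv"))
  for (nm in c("dose_era", "metadata")) {
    dt <- utils::read.csv(file.path(fx$dir, paste0(nm, ".csv")))
    utils::write.csv(dt[0, , drop = FALSE], file.path(fx$dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  s <- structural_report(open_dataset(fx$dir))
  pt <- s$per_table
  expect_identical(pt$note[pt$table == "dose_era"], "derived-table-not-populated")
  expect_identical(pt$note[pt$table == "note"], "free-text-capture-gap")
  expect_identical(pt$note[pt$table == "metadata"], "none")  # empty, not derived
})

test_that("appending one record moves a table from empty to available and changes nothing else", {
  fx <- make_39_dataset(0, 1, seed = 9)
  h <- open_dataset(fx$dir)
  s0 <- structural_report(h)
  expect_identical(s0$per_table$status[s0$per_table$table == fx$empty], "empty")

  f <- file.path(fx$dir, paste0(fx$empty, ".csv"))
  hdrs <- strsplit(readLines(f)[1], ",")[[1]]
  cat(paste(rep("1", length(hdrs)), collapse = ","), "\n", sep = "", file = f, append = TRUE)
  s1 <- structural_report(open_dataset(fx$dir))
  expect_identical(s1$per_table$status[s1$per_table$table == fx$empty], "available")
  expect_identical(s1$n_empty, s0$n_empty - 1L)
  expect_identical(s1$n_available, s0$n_available + 1L)
  same <- s0$per_table$table != fx$empty
  expect_identical(s1$per_table$status[same], s0$per_table$status[same])
})

test_that("tables present but not in the manifest are reported separately", {
  fx <- make_39_dataset(0, 0)
  utils::write.csv(data.frame(x = 1), file.path(fx$dir, "local_extras.csv"),
                   row.names = FALSE)
  s <- structural_report(open_dataset(fx$dir))
  expect_identical(s$unexpected_tables, "local_extras")
  expect_false("local_extras" %in% s$per_table$table)
})
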