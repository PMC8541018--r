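test_that("symbol normalization strips, uppercases, applies aliases, and is idempotent", {
  expect_equal(normalize_symbol("Trpv1"), "TRPV1")
  expect_equal(normalize_symbol("PPARG"), "PPARG")
  expect_equal(normalize_symbol(" cb2 ", alias_map = c(CB2 = "CNR2")), "CNR2")
  expect_error(normalize_symbol("  "), "empty")
  expect_error(normalize_symbol(c("A", "", "B")), "position 2")

  set.seed(42)
  raw <- c("Trpv1", " faah", "GPR55 ", "cb2", "pparG", "a1B2c3")
  amap <- c(CB2 = "CNR2", CB1 = "CNR1")
  once <- normalize_symbol(raw, amap)
  expect_identical(normalize_symbol(once, amap), once)
})

test_that("affinity tables parse with unit conversion and row-order preservation", {
  f <- tmpfile_lines(c(
    "target,activity,unit,measure,mode,source",
    "Pparg,100,nM,EC50,full agonist,r1",
    "faah,1.52,uM,IC50,inhibitor,r2",
    "CNR2,34000,pM,Ki,partial agonist,r3"), ext = ".csv")
  rec <- suppressMessages(read_affinity_table(f))
  expect_equal(rec$target_symbol, c("PPARG", "FAAH", "CNR2"))
  expect_equal(rec$activity_value_nM, c(100, 1520, 34))
  expect_equal(rec$activity_measure, c("EC50", "IC50", "Ki"))

  # unit suffix inside the activity field, no unit column
  f2 <- tmpfile_lines(c("target\tactivity\tmeasure\tmode",
                        "TRPV1\t2 µM\tEC50\tfull agonist"))
  rec2 <- suppressMessages(read_affinity_table(f2))
  expect_equal(rec2$activity_value_nM, 2000)

  # header-only file -> empty record list
  f3 <- tmpfile_lines("target,activity,unit,measure,mode", ext = ".csv")
  expect_equal(nrow(suppressMessages(read_affinity_table(f3))), 0L)
})

test_that("affinity parsing rejects bad rows with row and column named", {
  f <- tmpfile_lines(c("target,activity,unit,measure,mode",
                       "A,100,nM,Ki,inhibitor",
                       "B,abc,nM,Ki,inhibitor"), ext = ".csv")
  expect_error(suppressMessages(read_affinity_table(f)), "row 2.*activity")
  f2 <- tmpfile_lines(c("target,activity,unit,measure,mode",
                        "A,100,furlongs,Ki,inhibitor"), ext = ".csv")
  expect_error(suppressMessages(read_affinity_table(f2)), "unit")
  f3 <- tmpfile_lines(c("target,activity,unit,measure,mode",
                        "A,-5,nM,Ki,inhibitor"), ext = ".csv")
  expect_error(suppressMessages(read_affinity_table(f3)), "non-positive")
  f4 <- tmpfile_lines(c("target,activity,unit,mode", "A,5,nM,inhibitor"),
                      ext = ".csv")
  expect_error(suppressMessages(read_affinity_table(f4)), "measure")
})

test_that("association tables collapse duplicates by max score and filter on min_score", {
  f <- tmpfile_lines(c("symbol\toverall_score",
                       "TRPV1\t0.5", "FAAH\t0.2", "FAAH\t0.7",
                       "PPARG\t0.9", "CNR2\t0.05"))
  tab <- suppressMessages(read_association_table(f, "osteoarthritis"))
  expect_s3_class(tab, "association_table")
  expect_equal(nrow(tab$entries), 4L)
  expect_equal(tab$entries$score[tab$entries$symbol == "FAAH"], 0.7)

  # min_score excludes strictly-below entries
  tab2 <- suppressMessages(read_association_table(f, "oa", min_score = 0.5))
  expect_setequal(tab2$entries$symbol, c("TRPV1", "FAAH", "PPARG"))
  tab3 <- suppressMessages(read_association_table(f, "oa", min_score = 1))
  expect_equal(nrow(tab3$entries), 0L)

  # scoreless dialect
  f2 <- tmpfile_lines(c("symbol", "trpv1", "FAAH", "TRPV1"))
  tab4 <- suppressMessages(read_association_table(f2, "np"))
  expect_equal(tab4$entries$symbol, c("FAAH", "TRPV1"))
  expect_true(all(is.na(tab4$entries$score)))

  # invalid scores rejected
  f3 <- tmpfile_lines(c("symbol\toverall_score", "A\t1.2"))
  expect_error(suppressMessages(read_association_table(f3, "x")), "\\[0,1\\]")
})

test_that("edge lists are canonicalized: self-loops dropped, duplicates merged by max", {
  f <- tmpfile_lines(c("protein1 protein2 combined_score",
                       "A B 500", "B A 700", "C C 900"))
  e <- suppressMessages(read_edge_list(f))
  expect_equal(nrow(e), 1L)
  expect_equal(e$node_a, "A")
  expect_equal(e$node_b, "B")
  expect_equal(e$combined_score, 700L)

  f2 <- tmpfile_lines(c("protein1\tprotein2\tcombined_score",
                        "TRPV1\ttrpa1\t999"))
  e2 <- suppressMessages(read_edge_list(f2))
  expect_equal(e2$node_a, "TRPA1")
  expect_equal(e2$node_b, "TRPV1")

  f3 <- tmpfile_lines("protein1 protein2 combined_score")
  expect_equal(nrow(suppressMessages(read_edge_list(f3))), 0L)

  f4 <- tmpfile_lines(c("protein1 protein2 combined_score", "A B 1500"))
  expect_error(suppressMessages(read_edge_list(f4)), "\\[0, 1000\\]")
  f5 <- tmpfile_lines(c("protein1 protein2 combined_score", "A B 10.5"))
  expect_error(suppressMessages(read_edge_list(f5)), "integer")
})

test_that("edge-list output never contains self-loops or duplicate canonical pairs", {
  set.seed(5)
  for (trial in 1:20) {
    syms <- sample(LETTERS, 8)
    rows <- data.frame(protein1 = sample(syms, 40, TRUE),
                       protein2 = sample(syms, 40, TRUE),
                       combined_score = sample(0:1000, 40, TRUE))
    f <- tempfile()
    write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
    e <- suppressMessages(read_edge_list(f))
    expect_true(all(e$node_a < e$node_b))
    expect_false(any(duplicated(paste(e$node_a, e$node_b))))
  }
})

test_that("GMT parsing normalizes and deduplicates members and reports bad lines", {
  f <- tmpfile_lines(c("GO:1\tdesc one\tTRPV1\tTRPA1",
                       "GO:2\tdesc two\tA\ta\tB"), ext = ".gmt")
  gs <- read_gmt(f)
  expect_s3_class(gs, "gene_set_collection")
  expect_length(gs, 2L)
  expect_equal(gs[["GO:2"]]$members, c("A", "B"))

  f2 <- tmpfile_lines(c("GO:1\tdesc\tA", "GO:X\tdesc"), ext = ".gmt")
  expect_error(read_gmt(f2), "line 2")
  f3 <- tmpfile_lines(c("GO:1\tdesc\tA", "GO:1\tdesc\tB"), ext = ".gmt")
  expect_error(read_gmt(f3), "duplicate")
})

test_that("write/read round trips reproduce every parsed table field-by-field", {
  # affinity
  f <- tmpfile_lines(c("target,activity,unit,measure,mode,source",
                       "PPARG,0.1,uM,EC50,full agonist,r1",
                       "FAAH,1520,nM,IC50,inhibitor,r2"), ext = ".csv")
  rec <- suppressMessages(read_affinity_table(f))
  f2 <- tempfile(); write_affinity_table(rec, f2)
  expect_identical(suppressMessages(read_affinity_table(f2)), rec)

  # association
  fa <- tmpfile_lines(c("symbol\toverall_score", "TRPV1\t0.5", "FAAH\t0.7"))
  tab <- suppressMessages(read_association_table(fa, "oa"))
  fa2 <- tempfile(); write_association_table(tab, fa2)
  expect_identical(suppressMessages(read_association_table(fa2, "oa")), tab)

  # edges
  fe <- tmpfile_lines(c("protein1 protein2 combined_score", "A B 500", "A C 900"))
  e <- suppressMessages(read_edge_list(fe))
  fe2 <- tempfile(); write_edge_list(e, fe2)
  expect_identical(suppressMessages(read_edge_list(fe2)), e)

  # gmt
  fg <- tmpfile_lines(c("GO:1\td1\tA\tB", "GO:2\td2\tC\tD\tE"), ext = ".gmt")
  gs <- read_gmt(fg)
  fg2 <- tempfile(); write_gmt(gs, fg2)
  expect_identical(read_gmt(fg2), gs)
})
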