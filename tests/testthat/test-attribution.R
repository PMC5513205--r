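test_that("KO rows follow the at-least-half-of-subjects rule", {
  fx <- attribution_fixture()
  m <- build_attribution(fx$records, fx$config, fx$tree, n_subjects = 15)
  kos <- m$row_info$id[m$row_info$type == "ko"]
  expect_true("K00134" %in% kos)   # 15 subjects
  expect_true("K00626" %in% kos)   # exactly 8 = ceiling(15/2)
  expect_false("K01689" %in% kos)  # 7 subjects: dropped as a row
  expect_false("K00248" %in% kos)  # 2 subjects
  # but the dropped KO still counts towards its pathway row
  gly <- m$abundance["glycolysis", "total"]
  k134 <- m$abundance["K00134", "total"]
  expect_gt(gly, k134)
})

test_that("genus columns follow the at-least-two-subjects rule", {
  fx <- attribution_fixture()
  m <- build_attribution(fx$records, fx$config, fx$tree, n_subjects = 15)
  genera <- m$col_info$id[m$col_info$type == "genus"]
  expect_true("g__Faecalibacterium" %in% genera)
  expect_true("g__Bacteroides" %in% genera)
  expect_true("g__Roseburia" %in% genera)       # exactly 2 subjects: retained
  expect_false("g__Ruminococcus" %in% genera)   # 1 subject: dropped
})

test_that("rows and columns conserve totals over retained and dropped members", {
  fx <- attribution_fixture()
  m <- build_attribution(fx$records, fx$config, fx$tree, n_subjects = 15)
  A <- m$abundance
  # pathway row >= any member KO row; phylum column >= any member genus column
  expect_true(all(A["glycolysis", ] >= A["K00134", ] - 1e-15))
  expect_true(all(A["butyrogenesis", ] >= A["K00626", ] - 1e-15))
  expect_true(all(A[, "p__Firmicutes"] >= A[, "g__Faecalibacterium"] - 1e-15))
  # phylum total equals the sum over ALL its genera (incl. dropped ones)
  firmi <- c("g__Faecalibacterium", "g__Roseburia", "g__Ruminococcus")
  kept <- intersect(firmi, colnames(A))
  dropped_mass <- A["total", "p__Firmicutes"] - sum(A["total", kept])
  expect_gte(dropped_mass, -1e-15)
  # grand total is the sum over pathway rows and over phylum columns alike
  pw_rows <- m$row_info$id[m$row_info$type == "pathway"]
  ph_cols <- m$col_info$id[m$col_info$type == "phylum"]
  expect_equal(sum(A[pw_rows, "total"]), A["total", "total"])
  expect_equal(sum(A["total", ph_cols]), A["total", "total"])
  # log display values are finite even for empty cells
  expect_true(all(is.finite(m$values)))
})

test_that("single-contributor pathway: phylum total equals the genus column", {
  tr <- fixture_tree()
  cfg <- pathway_config(list(butyrogenesis = c("K00626", "K00248")))
  rec <- rbind(
    make_records(c("g__Faecalibacterium|K00626" = 30,
                   "g__Faecalibacterium|K00248" = 10,
                   "g__Bacteroides|K00001" = 60), "S01", "MP"),
    make_records(c("g__Faecalibacterium|K00626" = 50,
                   "g__Bacteroides|K00001" = 50), "S02", "MP")
  )
  m <- build_attribution(rec, cfg, tr, n_subjects = 2)
  expect_equal(m$abundance[, "p__Firmicutes"], m$abundance[, "g__Faecalibacterium"])
  expect_equal(unname(pathway_shares(m)), 1)
  expect_equal(unname(taxon_shares(m)["p__Firmicutes"]), 1)
})

test_that("pathway and taxon shares recover direct ratios and planted weights", {
  tr <- fixture_tree()
  cfg <- pathway_config(list(pw1 = "K00001", pw2 = "K00002"))
  rec <- rbind(
    make_records(c("g__Faecalibacterium|K00001" = 75,
                   "g__Bacteroides|K00002" = 25), "S01", "MP"),
    make_records(c("g__Faecalibacterium|K00001" = 75,
                   "g__Bacteroides|K00002" = 25), "S02", "MP")
  )
  m <- build_attribution(rec, cfg, tr, n_subjects = 2)
  expect_equal(unname(pathway_shares(m)), c(0.75, 0.25))
  expect_equal(sum(pathway_shares(m)), 1, tolerance = 1e-9)
  expect_equal(unname(taxon_shares(m)[c("p__Bacteroidetes", "p__Firmicutes")]),
               c(0.25, 0.75))
  # shares invariant under uniform depth rescaling
  rec10 <- rec
  rec10$weight <- rec10$weight * 10L
  m10 <- build_attribution(rec10, cfg, tr, n_subjects = 2)
  expect_equal(pathway_shares(m10), pathway_shares(m))
})

test_that("attribution retention is monotone under added records", {
  fx <- attribution_fixture()
  m1 <- build_attribution(fx$records, fx$config, fx$tree, n_subjects = 15)
  more <- rbind(fx$records,
                make_records(c("g__Faecalibacterium|K01689" = 10), "S09", "MP"),
                make_records(c("g__Ruminococcus|K00626" = 5), "S09", "MP"))
  m2 <- build_attribution(more, fx$config, fx$tree, n_subjects = 15)
  kept_rows1 <- m1$row_info$id[m1$row_info$type == "ko"]
  kept_rows2 <- m2$row_info$id[m2$row_info$type == "ko"]
  expect_true(all(kept_rows1 %in% kept_rows2))
  kept_cols1 <- m1$col_info$id[m1$col_info$type == "genus"]
  kept_cols2 <- m2$col_info$id[m2$col_info$type == "genus"]
  expect_true(all(kept_cols1 %in% kept_cols2))
  # the 8th K01689 subject and 2nd Ruminococcus subject flip retention
  expect_true("K01689" %in% kept_rows2)
  expect_true("g__Ruminococcus" %in% kept_cols2)
})

test_that("pathway config validates and round-trips through its text format", {
  expect_error(pathway_config(list(a = "K1", b = "K1")),
               class = "mgmp_config_error")
  expect_error(pathway_config(setNames(list("K1", "K2"), c("a", "a"))),
               class = "mgmp_config_error")
  cfg <- default_pathways()
  f <- tempfile(fileext = ".tsv")
  write_pathways(cfg, f)
  back <- read_pathways(f)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(build_attribution(make_records(c("g__T001|K9" = 1)),
                                 structure(list(), class = "pathway_config"),
                                 fixture_tree()),
               class = "mgmp_config_error")
})
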