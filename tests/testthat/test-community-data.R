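test_that("shared files round-trip exactly and reject malformed input", {
  tab <- random_table(2, 3, seed = 11)
  f <- withr::local_tempfile(fileext = ".shared")
  write_shared(tab, f)
  back <- read_shared(f)
  expect_identical(back$counts, tab$counts)
  expect_equal(dim(back$counts), c(2L, 3L))

  # numOtus disagreeing with the OTU columns present
  bad <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\ta\tb\tc\td",
               "0.03\ts1\t3\t1\t2\t3\t4",
               "0.03\ts2\t3\t4\t3\t2\t1"), bad)
  expect_error(read_shared(bad), "numOtus")

  # non-integer and negative counts
  bad2 <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\ta\tb",
               "0.03\ts1\t2\t1.5\t2",
               "0.03\ts2\t2\t1\t2"), bad2)
  expect_error(read_shared(bad2), "nonnegative integers")

  # two OTU-definition labels
  bad3 <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\ta\tb",
               "0.03\ts1\t2\t1\t2",
               "0.05\ts2\t2\t1\t2"), bad3)
  expect_error(read_shared(bad3), "label")

  bad4 <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("Group\tlabel\tnumOtus\ta", "s1\t0.03\t1\t5"), bad4)
  expect_error(read_shared(bad4), "header")
})

test_that("community_table enforces its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(community_table(m), "community_table")
  expect_error(community_table(unname(m)), "rownames")
  m2 <- m; m2[1, ] <- c(-1L, 3L)
  expect_error(community_table(m2), "nonnegative")
  m3 <- m; m3[2, ] <- 0L
  expect_error(community_table(m3), "positive library size")
  m4 <- m; rownames(m4) <- c("a", "a")
  expect_error(community_table(m4), "unique")
})

test_that("taxonomy parsing strips confidences, fills unclassified tails, round-trips", {
  tax <- taxonomy_map(
    c("otu1", "otu2", "otu3"),
    c("Bacteria(100);Bacteroidetes(98);Bacteroidia(97);Bacteroidales(90);Prevotellaceae(88);Prevotella(85);",
      "Bacteria;Firmicutes;Clostridia",
      "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;unclassified"))
  expect_equal(tax$genus[1], "Prevotella")
  expect_equal(tax$phylum[1], "Bacteroidetes")
  # missing tail ranks propagate the nearest classified parent
  expect_equal(tax$order[2], "unclassified_Clostridia")
  expect_equal(tax$genus[2], "unclassified_Clostridia")
  # explicit 'unclassified' is rewritten with its parent
  expect_equal(tax$genus[3], "unclassified_Methanobacteriaceae")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, f)
  back <- read_taxonomy(f)
  expect_equal(back, tax)
})

test_that("sample metadata validates the design constraints", {
  md <- data.frame(sample_id = c("a", "b"), vessel = c("C1", "C1"),
                   condition = "control", day = c(1, 1),
                   hours_post_feeding = c(4, 12), time_h = c(4, 12))
  expect_s3_class(sample_metadata(md), "sample_metadata")

  bad <- md; bad$time_h[2] <- 13
  expect_error(sample_metadata(bad), "time_h must equal")
  bad <- md; bad$condition <- c("control", "treatment")
  expect_error(sample_metadata(bad), "constant within a vessel")
  bad <- md; bad$hours_post_feeding <- c(4, 4); bad$time_h <- c(4, 4)
  expect_error(sample_metadata(bad), "unique")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(sample_metadata(md), f)
  expect_equal(as.data.frame(read_metadata(f)), as.data.frame(md))
})

test_that("PHYLIP square distance files round-trip within write precision", {
  tab <- random_table(5, 12, seed = 3)
  d <- pairwise_distances(tab, "theta_yc")
  f <- withr::local_tempfile(fileext = ".dist")
  write_dist(d, f)
  back <- read_dist(f)
  expect_equal(back, d, tolerance = 1e-10)
  expect_identical(rownames(back), rownames(d))
})

test_that("rank aggregation sums groups and conserves sample totals", {
  m <- matrix(c(3L, 1L, 4L, 2L, 0L, 6L), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tab <- community_table(m)
  tax <- taxonomy_map(c("o1", "o2", "o3"),
                      c("Bacteria;P1;c;o;f;GenA", "Bacteria;P1;c;o;f;GenA",
                        "Bacteria;P2;c2;o2;f2;GenB"))
  g <- aggregate_to_rank(tab, tax, "genus")
  expect_equal(sort(otu_ids(g)), c("GenA", "GenB"))
  expect_equal(unname(g$counts[, "GenA"]), c(4L, 2L))
  expect_equal(rowSums(g$counts), rowSums(m))

  # one phylum spanning all OTUs of a table collapses to library sizes
  tax1 <- taxonomy_map(c("o1", "o2", "o3"),
                       rep("Bacteria;P1;c;o;f;g", 3))
  p <- aggregate_to_rank(tab, tax1, "phylum")
  expect_equal(ncol(p$counts), 1L)
  expect_equal(unname(p$counts[, 1]), unname(rowSums(m)))

  # random table: totals conserved at every rank
  rt <- random_table(5, 8, seed = 21)
  lin <- paste0("Bacteria;P", rep(1:2, 4), ";C", rep(1:4, 2), ";o;f;G",
                1:8)
  rtax <- taxonomy_map(otu_ids(rt), lin)
  for (rk in c("phylum", "class", "genus"))
    expect_equal(rowSums(aggregate_to_rank(rt, rtax, rk)$counts),
                 rowSums(rt$counts))

  expect_error(aggregate_to_rank(tab, tax, "species"), "unknown rank")
  expect_error(aggregate_to_rank(rt, tax, "genus"), "unmapped")
})

test_that("rarefying subsamples without replacement to exact depth", {
  m <- matrix(c(1000L, 0L, 0L, 200L, 150L, 150L), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  tab <- community_table(m)
  r <- rarefy(tab, 100, seed = 1)
  expect_equal(unname(r$counts[1, ]), c(100L, 0L, 0L))
  expect_equal(unname(rowSums(r$counts)), c(100L, 100L))

  # depth equal to the row sum leaves the sample unchanged
  one <- community_table(m[2, , drop = FALSE])
  expect_identical(rarefy(one, 500, seed = 2)$counts, one$counts)

  expect_error(rarefy(tab, 0), "positive integer")
  expect_warning(r2 <- rarefy(tab, 600, seed = 1), "dropping 1 sample")
  expect_equal(nrow(r2$counts), 1L)

  # reproducibility under a fixed seed
  expect_identical(rarefy(tab, 100, seed = 7)$counts,
                   rarefy(tab, 100, seed = 7)$counts)
})

test_that("rarefied counts follow the hypergeometric expectation", {
  counts <- c(a = 50L, b = 30L, c = 20L)
  m <- matrix(counts, 1, dimnames = list("s", names(counts)))
  tab <- community_table(m)
  depth <- 25
  draws <- vapply(seq_len(2000), function(i)
    rarefy(tab, depth, seed = i)$counts[1, "a"], 0L)
  expected <- depth * counts[["a"]] / sum(counts)  # 12.5
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se + 1e-12)
})

test_that("rarefying is distribution-invariant to OTU column permutation", {
  m <- matrix(c(40L, 25L, 10L, 5L), 1, 4,
              dimnames = list("s", c("a", "b", "c", "d")))
  tab <- community_table(m)
  perm <- c("c", "a", "d", "b")
  tabp <- community_table(m[, perm, drop = FALSE])
  da <- vapply(1:800, function(i) rarefy(tab, 20, seed = i)$counts[1, "a"],
               0L)
  dp <- vapply(801:1600, function(i)
    rarefy(tabp, 20, seed = i)$counts[1, "a"], 0L)
  se <- sqrt(var(da) / length(da) + var(dp) / length(dp))
  expect_lt(abs(mean(da) - mean(dp)), 4 * se)
})

test_that("singleton OTUs are removed and nothing else", {
  m <- matrix(c(1L, 5L, 0L, 0L, 3L, 1L), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("single", "keep", "also")))
  # column 'single' totals 1, column 'also' totals 1
  tab <- community_table(m)
  f <- filter_singletons(tab)
  expect_equal(otu_ids(f), "keep")

  ns <- random_table(4, 6, seed = 5)
  expect_equal(ncol(filter_singletons(ns)$counts),
               sum(colSums(ns$counts) != 1))
  nosingle <- community_table(ns$counts[, colSums(ns$counts) != 1,
                                        drop = FALSE])
  expect_identical(filter_singletons(nosingle)$counts, nosingle$counts)
})
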