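test_that("injection-site discrepancies recompute from rounded coordinates", {
  tab <- load_injection_table()
  expect_identical(nrow(tab), 17L)
  dt <- discrepancy_table(tab)
  # coordinates are recorded rounded to 0.1 mm, which can move a recomputed
  # distance by up to sqrt(3) * 0.1 mm; observed deviations stay well below
  # that bound and most rows land within half the rounding step
  dev <- abs(dt$table$discrepancy_mm - tab$recorded_discrepancy_mm)
  expect_true(all(dev <= 0.1))
  expect_gte(sum(dev <= 0.05), 12L)
  cj94 <- dt$table[tab$case == "CJ94" & tab$tracer == "DY", ]
  expect_equal(round(cj94$discrepancy_mm, 2), 1.36)
  cj71 <- dt$table[tab$case == "CJ71" & tab$tracer == "DY", ]
  expect_equal(round(cj71$discrepancy_mm, 2), 0.22)
  cj71fe <- dt$table[tab$case == "CJ71" & tab$tracer == "FE", ]
  expect_lt(abs(cj71fe$discrepancy_mm - 0.32), 0.01)
  # mean of recomputed distances and of the recorded column itself
  expect_lt(abs(dt$mean_mm - 0.6), 0.05)
  expect_equal(round(mean(tab$recorded_discrepancy_mm), 3), 0.603)
  one <- data.frame(auto_ml = 1, auto_ap = -2, auto_dv = 3,
                    expert_ml = 1, expert_ap = -2, expert_dv = 3)
  expect_equal(discrepancy_table(one)$mean_mm, 0)
  expect_error(euclidean_discrepancy(c(1, NA, 0), c(0, 0, 0)), "finite")
})

mk_tab <- function(inj, area, pct) data.frame(injection = inj, area = area,
                                              percent = pct,
                                              stringsAsFactors = FALSE)

test_that("percentage agreement reproduces the textbook Pearson correlation", {
  set.seed(30)
  e <- mk_tab("i1", paste0("A", 1:10), runif(10, 0, 30))
  a <- mk_tab("i1", paste0("A", 1:10), runif(10, 0, 30))
  res <- percentage_agreement(e, a)
  # two-pass textbook formula
  x <- e$percent[order(e$area)]; y <- a$percent[order(a$area)]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(res$pearson_r - r_hand), 1e-12)
  expect_identical(res$n_pairs, 10L)
  # exact and scaled agreement both give r = 1
  expect_equal(percentage_agreement(e, e)$pearson_r, 1.0)
  a2 <- e; a2$percent <- 2 * e$percent
  expect_equal(percentage_agreement(e, a2)$pearson_r, 1.0)
  # symmetry under exchanging the tables
  expect_equal(percentage_agreement(a, e)$pearson_r, res$pearson_r)
  expect_error(percentage_agreement(e[1:2, ], a[1:2, ]), "InsufficientData")
})

test_that("interval-valued expert percentages are scored at their midpoint", {
  e <- mk_tab("i1", c("A1", "A2", "A3"), c("0.05-0.1", "2.5", "10"))
  a <- mk_tab("i1", c("A1", "A2", "A3"), c(0.075, 2.5, 10))
  expect_equal(percentage_agreement(e, a)$pearson_r, 1.0)
})

test_that("supergroup merging pools member-area percentages", {
  e <- mk_tab("i1", c("AuA1", "AuR", "V1", "V2"), c(1, 2, 10, 20))
  a <- mk_tab("i1", c("AuA1", "AuR", "V1", "V2"), c(2, 1, 10, 20))
  g <- list("core and belt" = c("AuA1", "AuR"))
  res <- percentage_agreement(e, a, grouping = g)
  expect_identical(res$n_pairs, 3L)
  merged <- res$pairs[res$pairs$area == "core and belt", ]
  expect_equal(merged$percent_expert, 3)
  expect_equal(merged$percent_auto, 3)
  expect_error(percentage_agreement(e, a, grouping = list(g1 = "nope")),
               "ConfigError")
  expect_true("core and belt" %in% names(load_supergroups()))
})

test_that("sparse-connection concordance counts match brute force", {
  e <- mk_tab("i1", c("A1", "A2"), c(0.04, 0.2))
  a <- mk_tab("i1", c("A1", "A2"), c(0.01, 0.2))
  sc <- sparse_concordance(e, a, threshold = 0.05)
  expect_identical(sc$n_expert_sparse, 1L)
  expect_identical(sc$n_both_sparse, 1L)
  expect_equal(sc$fraction_sparse, 1.0)
  # all-zero tables are fully concordant
  z <- mk_tab("i1", paste0("A", 1:4), rep(0, 4))
  scz <- sparse_concordance(z, z)
  expect_equal(scz$fraction_sparse, 1.0)
  expect_equal(scz$fraction_zero, 1.0)
  # random tables against a filter-and-count oracle
  set.seed(31)
  e <- mk_tab("i1", paste0("A", 1:100), round(runif(100, 0, 0.2), 2))
  a <- mk_tab("i1", paste0("A", 1:100), round(runif(100, 0, 0.2), 2))
  sc <- sparse_concordance(e, a, threshold = 0.05)
  eo <- e$percent[order(e$area)]; ao <- a$percent[order(a$area)]
  expect_identical(sc$n_expert_sparse, sum(eo <= 0.05))
  expect_identical(sc$n_both_sparse, sum(eo <= 0.05 & ao <= 0.05))
  expect_identical(sc$n_expert_zero, sum(eo == 0))
  expect_identical(sc$n_both_zero, sum(eo == 0 & ao == 0))
})
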