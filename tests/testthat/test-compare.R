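test_that("closest-method competition uses absolute error with the tie rule", {
  cm <- epithreshold:::closest_method
  # MFL and DMP tie at |1/3 - 0.30|; lexicographic rule picks DMP, flagged
  res <- cm(c(MFL = abs(1 / 3 - 0.3), QMF = abs(1 / 4 - 0.3),
              DMP = abs(1 / 3 - 0.3)))
  expect_equal(res$method, "DMP")
  expect_true(res$tie)
  # at lambda_c = 0.25 the QMF prediction 1/4 is exact
  res <- cm(c(MFL = abs(1 / 3 - 0.25), QMF = 0, DMP = abs(1 / 3 - 0.25)))
  expect_equal(res$method, "QMF")
  expect_false(res$tie)
  # undefined DMP is excluded, not imputed
  res <- cm(c(MFL = 0.1, QMF = 0.2, DMP = NA))
  expect_equal(res$method, "MFL")

  # absolute and relative error induce the same winner (shared lambda_c > 0)
  set.seed(1)
  for (i in 1:20) {
    e <- stats::runif(3)
    names(e) <- c("MFL", "QMF", "DMP")
    lc <- stats::runif(1, 0.1, 1)
    expect_equal(cm(e)$method, cm(e / lc)$method)
  }
})

test_that("records assemble correctly, including the tree degenerate path", {
  g <- graph_fixture("regular", n = 40, k = 4, seed = 1)
  rec <- build_record(g, "reg4", lambda_c = 0.30)
  expect_equal(rec$abs_err_mfl, abs(1 / 3 - 0.30))
  expect_equal(rec$abs_err_mfl, rec$abs_err_dmp, tolerance = 1e-8)  # regular: MFL = DMP
  expect_equal(rec$closest_method, "DMP")                            # tie rule
  expect_true(rec$closest_tie)
  expect_equal(rec$rel_err_qmf, abs(0.25 - 0.30) / 0.30, tolerance = 1e-8)

  tree <- path_graph(10)
  rec <- build_record(tree, "tree", lambda_c = 0.5)
  expect_true(is.na(rec$lc_dmp))
  expect_true(is.na(rec$abs_err_dmp))
  expect_true(rec$closest_method %in% c("MFL", "QMF"))
})

test_that("closest-method frequencies are proper fractions", {
  recs <- data.frame(closest_method = c("DMP", "DMP", "DMP", "MFL"))
  f <- closest_frequency(recs)
  expect_equal(unname(f), c(0.25, 0, 0.75))
  expect_equal(sum(f), 1)
  expect_equal(unname(closest_frequency(data.frame(closest_method = "QMF"))["QMF"]), 1)
  expect_error(closest_frequency(data.frame(closest_method = NA_character_)))
})

test_that("binned error curves honor the window lattice and empty bins", {
  recs <- data.frame(r = c(-0.21, -0.19, 0.32), c = c(0.1, 0.2, 0.3),
                     Q = c(0.5, 0.5, 0.5),
                     rel_err_mfl = c(0.1, 0.3, 0.4),
                     rel_err_qmf = c(0.2, 0.2, 0.2),
                     rel_err_dmp = c(0.3, 0.1, 0.5))
  tab <- binned_errors(recs, "r")
  row <- tab[abs(tab$x + 0.2) < 1e-9, ]
  expect_equal(row$rel_err_mfl, 0.2)
  expect_equal(row$count, 2)
  empty <- tab[abs(tab$x - 0.1) < 1e-9, ]
  expect_equal(empty$count, 0)
  expect_true(is.na(empty$rel_err_mfl))

  # delta override widens the window
  tab2 <- binned_errors(recs, "r", delta_x = 0.2)
  expect_equal(tab2$count[abs(tab2$x + 0.2) < 1e-9], 2)

  # undefined covariates are excluded with a count
  recs$r[3] <- NA
  tab3 <- binned_errors(recs, "r")
  expect_equal(attr(tab3, "excluded"), 1)

  # pooled-mean consistency: count-weighted mean of bin means = grand mean
  recs2 <- data.frame(r = stats::runif(30, -0.5, 0.5),
                      rel_err_mfl = stats::runif(30),
                      rel_err_qmf = stats::runif(30),
                      rel_err_dmp = stats::runif(30))
  tab4 <- binned_errors(recs2, "r")
  ok <- tab4$count > 0
  expect_equal(sum(tab4$rel_err_mfl[ok] * tab4$count[ok]) / sum(tab4$count[ok]),
               mean(recs2$rel_err_mfl), tolerance = 1e-12)
})

test_that("size-scaling tables are deterministic given the master seed", {
  t1 <- size_scaling_experiment(3.5, c(300, 600), n_realizations = 200,
                                master_seed = 5, grid_points = 9)
  t2 <- size_scaling_experiment(3.5, c(300, 600), n_realizations = 200,
                                master_seed = 5, grid_points = 9)
  expect_identical(t1, t2)
  expect_true(all(t1$lc_qmf <= t1$lc_dmp + 1e-10))
})
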