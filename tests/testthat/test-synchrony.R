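test_that("perfectly and anti-correlated pairs are handled by contract", {
  set.seed(81)
  x <- rnorm(400)
  ident <- trace_matrix(rbind(a = x, b = x), 10, "dff")
  bout <- list(start_frame = 0, end_frame = 400, label = "AW")
  res <- boutwise_correlation(ident, bout)
  expect_equal(res$Z_R[1, 2], fisher_z(1 - 1e-6))  # clipped, ~7.254
  expect_equal(res$per_cell_mean_pos_zr[["a"]], fisher_z(1 - 1e-6))

  anti <- trace_matrix(rbind(a = x, b = -x), 10, "dff")
  res2 <- boutwise_correlation(anti, bout)
  expect_true(all(is.na(res2$per_cell_mean_pos_zr)))  # no positive partners
  expect_true(is.nan(res2$state_mean_zr) || is.na(res2$state_mean_zr))
})

test_that("short bouts are skipped and flat cells excluded pairwise", {
  set.seed(82)
  tm <- trace_matrix(matrix(rnorm(3 * 400), 3,
                            dimnames = list(c("a", "b", "flat"), NULL)),
                     10, "dff")
  tm$values[3, 1:400] <- 2
  expect_warning(out <- boutwise_correlation(
    tm, list(start_frame = 0, end_frame = 50, label = "AW")), "skipped")
  expect_null(out)
  res <- boutwise_correlation(tm, list(start_frame = 0, end_frame = 400,
                                       label = "AW"))
  expect_true(all(is.na(res$R[3, ])))
  expect_true(is.na(res$per_cell_mean_pos_zr[["flat"]]))
  expect_false(is.na(res$R[1, 2]))
})

test_that("synchrony is invariant to uniform additive shifts", {
  set.seed(83)
  vals <- matrix(rnorm(10 * 600), 10)
  bout <- list(start_frame = 100, end_frame = 500, label = "AW")
  base <- boutwise_correlation(trace_matrix(vals, 10, "dff"), bout)
  shifted <- vals
  shifted[, 101:500] <- shifted[, 101:500] + 3.7
  shift <- boutwise_correlation(trace_matrix(shifted, 10, "dff"), bout)
  expect_equal(base$R, shift$R, tolerance = 1e-12)
  expect_equal(base$state_mean_zr, shift$state_mean_zr, tolerance = 1e-12)
})

test_that("independent noise gives the null level of mean positive Z_R", {
  # Monte-Carlo oracle: direct cor/atanh pipeline on fresh iid matrices.
  set.seed(84)
  n_cells <- 30; nf <- 2000
  oracle <- vapply(1:25, function(i) {
    x <- matrix(rnorm(n_cells * nf), ncol = n_cells)
    R <- cor(x); diag(R) <- NA
    Z <- atanh(pmin(pmax(R, -(1 - 1e-6)), 1 - 1e-6))
    mean(vapply(seq_len(n_cells), function(j) {
      pos <- which(R[j, ] > 0)
      mean(Z[j, pos])
    }, numeric(1)))
  }, numeric(1))
  tm <- trace_matrix(matrix(rnorm(n_cells * nf), n_cells), 10, "dff")
  res <- boutwise_correlation(tm, list(start_frame = 0, end_frame = nf,
                                       label = "AW"))
  expect_lt(abs(res$state_mean_zr - mean(oracle)),
            3 * sd(oracle) + 3 * sd(oracle) / sqrt(length(oracle)))
})

test_that("state summary averages bouts and compares groups two-way", {
  mk <- function(zr, label) {
    structure(list(state_mean_zr = zr, label = label, cell_ids = "x",
                   start_frame = 0), class = "synchrony_result")
  }
  same <- list(mk(0.1, "AW"), mk(0.1, "AW"), mk(0.1, "AW"))
  s1 <- state_summary(same)
  expect_equal(s1$table$mean_zr, 0.1)
  expect_equal(s1$table$sem_zr, 0)

  set.seed(85)
  groups <- list(
    control = c(lapply(rnorm(4, 0.10, 0.01), mk, label = "AW"),
                lapply(rnorm(4, 0.12, 0.01), mk, label = "NREMS")),
    narcoleptic = c(lapply(rnorm(4, 0.03, 0.01), mk, label = "AW"),
                    lapply(rnorm(4, 0.04, 0.01), mk, label = "NREMS")))
  s2 <- state_summary(groups)
  expect_equal(nrow(s2$table), 4)
  expect_false(is.null(s2$anova))
  expect_lt(s2$anova$A$p, 0.001)  # group effect dominates by construction
})

test_that("connectivity edges obey the R >= 0.6 band and pair counting", {
  set.seed(86)
  n <- 6
  x <- rnorm(500)
  vals <- do.call(rbind, replicate(n, x, simplify = FALSE))
  ids <- sprintf("c%d", 1:n)
  rownames(vals) <- ids
  tm <- trace_matrix(vals, 10, "dff")
  cents <- data.frame(cell_id = ids, x = runif(n, 0, 100), y = runif(n, 0, 100))
  res <- boutwise_correlation(tm, list(start_frame = 0, end_frame = 500,
                                       label = "EC"))
  map <- connectivity_map(res, cents)
  expect_equal(map$n_edges, n * (n - 1) / 2)  # fully synchronized population

  indep <- trace_matrix(matrix(rnorm(n * 500), n, dimnames = list(ids, NULL)),
                        10, "dff")
  res2 <- boutwise_correlation(indep, list(start_frame = 0, end_frame = 500,
                                           label = "AW"))
  expect_equal(connectivity_map(res2, cents)$n_edges, 0)
  expect_warning(m3 <- connectivity_map(res, cents[-1, ]), "missing centroids")
  expect_equal(m3$n_edges, (n - 1) * (n - 2) / 2)
})

test_that("EC bouts with shared drive out-synchronize HAW bouts", {
  s <- fx_narco()
  b <- s$bouts
  long_enough <- (b$end_frame - b$start_frame) >= 100
  ec <- which(b$label == "EC" & long_enough)
  haw <- which(b$label == "HAW" & long_enough)
  expect_gt(length(ec), 0)
  expect_gt(length(haw), 0)
  res_ec <- boutwise_correlation(s$zmat, b[ec[1], ])
  res_haw <- boutwise_correlation(s$zmat, b[haw[1], ])
  expect_gt(res_ec$state_mean_zr, res_haw$state_mean_zr)
  cents <- s$sim$centroids
  expect_gt(connectivity_map(res_ec, cents)$n_edges,
            connectivity_map(res_haw, cents)$n_edges)
})
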