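make_field_traj <- function(score, fix_cells) {
  nr <- nrow(score); nc <- ncol(score)
  g <- reference_grid(cbind(c(0, nc * 100 - 1), c(0, nr * 100 - 1)),
                      grain = 100, buffer = 0)
  # fix_cells: (row, col) 1-based; one fix at each cell center
  xy <- cbind((fix_cells[, 2] - 0.5) * 100, (fix_cells[, 1] - 0.5) * 100)
  traj <- hr_trajectory("a", seq_len(nrow(xy)) * 60, xy[, 1], xy[, 2])
  list(field = cell_field(g, score), traj = traj)
}

test_that("AUC hits its analytic anchors", {
  s <- matrix(0, 3, 3); s[1, 1] <- 2; s[3, 3] <- 1
  ft <- make_field_traj(s, rbind(c(1, 1), c(3, 3)))
  expect_equal(as.numeric(compute_auc(ft$field, ft$traj)), 1.0)
  ft0 <- make_field_traj(matrix(4, 3, 3), rbind(c(1, 1), c(3, 3)))
  expect_equal(as.numeric(compute_auc(ft0$field, ft0$traj)), 0.5)
  # multiple fixes in one cell count once (binary presence)
  ft2 <- make_field_traj(s, rbind(c(1, 1), c(1, 1), c(3, 3)))
  expect_equal(attr(compute_auc(ft2$field, ft2$traj), "n_presence"), 2L)
  expect_error(compute_auc(ft$field,
                           make_field_traj(s, expand.grid(1:3, 1:3) |>
                                             as.matrix())$traj),
               "undefined")
})

test_that("rank-sum AUC equals brute-force pair counting on random grids", {
  set.seed(51)
  for (i in 1:30) {
    nr <- sample(3:20, 1); nc <- sample(3:20, 1)
    score <- matrix(sample(0:9, nr * nc, replace = TRUE), nr, nc)
    n_fix <- sample(1:(nr * nc - 1), 1)
    cells <- unique(cbind(sample(nr, n_fix, TRUE), sample(nc, n_fix, TRUE)))
    if (nrow(cells) == nr * nc) cells <- cells[-1, , drop = FALSE]
    ft <- make_field_traj(score, cells)
    presence <- matrix(FALSE, nr, nc)
    presence[cells] <- TRUE
    expect_equal(as.numeric(compute_auc(ft$field, ft$traj)),
                 auc_bruteforce(score, presence), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(52)
  score <- matrix(rnorm(48), 6, 8)
  cells <- cbind(sample(6, 5, TRUE), sample(8, 5, TRUE))
  ft <- make_field_traj(score, cells)
  a0 <- as.numeric(compute_auc(ft$field, ft$traj))
  for (f in list(exp, function(x) rank(x, ties.method = "average"),
                 function(x) x^3 + 2 * x)) {
    s2 <- matrix(f(as.vector(score)), 6, 8)
    ft2 <- make_field_traj(s2, cells)
    expect_equal(as.numeric(compute_auc(ft2$field, ft2$traj)), a0,
                 tolerance = 1e-12)
  }
})

test_that("the AUC table covers every animal x estimator cell with covariates", {
  trs <- list(sim_small_gps(61, days = 6), sim_small_gps(62, days = 6))
  trs[[2]]$animal_id <- "A2"
  tab <- suppressWarnings(auc_table(trs, estimators = c("lkde", "bbmm",
                                                        "char", "mkde")))
  expect_equal(nrow(tab), 8)
  expect_true(all(!is.na(tab$auc)))
  expect_true(all(tab$auc > 0.5 & tab$auc <= 1))
  expect_equal(unique(tab$technology), "GPS")
  expect_equal(unique(tab$n_locations_class),
               as.character(n_locations_class(length(trs[[1]]))))

  # VHF: the movement-based KDE is recorded missing, never zero
  prm <- ou_params(duration_days = 40)
  vhf <- vhf_subsample(simulate_ou(prm, seed = 63), seed = 64)
  tabv <- suppressWarnings(auc_table(list(vhf), estimators = c("lkde",
                                                               "mkde")))
  expect_true(is.na(tabv$auc[tabv$estimator == "mkde"]))
  expect_match(tabv$note[tabv$estimator == "mkde"], "not estimable")
  expect_false(is.na(tabv$auc[tabv$estimator == "lkde"]))
})

test_that("location-count classes follow the printed bins", {
  expect_equal(as.character(n_locations_class(c(50, 100, 101, 500, 501,
                                                750, 1000, 1001))),
               c("<100", "<100", "101-500", "101-500", "501-1000",
                 "501-1000", "501-1000", ">1000"))
})

test_that("Kruskal-Wallis wraps the tie-corrected rank statistic", {
  g_id <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(kruskal_wallis(g_id)$H, 0)
  g15 <- split(rnorm(150), rep(1:15, each = 10))
  expect_equal(kruskal_wallis(g15)$df, 14)
  expect_error(kruskal_wallis(list(1:5)), "at least 2")
  # brute-force rank oracle with tie correction, two small groups
  a <- c(1.2, 3.4, 3.4, 5.6); b <- c(2.2, 3.4, 7.1)
  r <- rank(c(a, b))
  n <- length(r)
  H <- 12 / (n * (n + 1)) *
    (sum(r[1:4])^2 / 4 + sum(r[5:7])^2 / 3) - 3 * (n + 1)
  ties <- table(c(a, b))
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(list(a, b))$H, H, tolerance = 1e-12)
})

test_that("pairwise Welch t-tests carry the Bonferroni multiplier", {
  g <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  p <- pairwise_t_bonferroni(g)
  expect_true(all(p[upper.tri(p)] == 1))
  # 3 groups -> 3 comparisons: adjusted = min(1, 3 * raw)
  set.seed(53)
  g3 <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 3))
  p3 <- pairwise_t_bonferroni(g3)
  raw <- t.test(g3$a, g3$b)$p.value
  expect_equal(p3["a", "b"], min(1, 3 * raw), tolerance = 1e-12)
  # hand-computed Welch statistic for a crafted pair
  x <- c(2, 4, 6, 8); y <- c(1, 2, 3)
  se2 <- var(x) / 4 + var(y) / 3
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  raw2 <- 2 * pt(-abs(tstat), df)
  expect_equal(pairwise_t_bonferroni(list(x = x, y = y))["x", "y"],
               min(1, raw2), tolerance = 1e-12)
})

test_that("logit behaves on (0,1) and rejects the boundary", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.9), 2.197224577, tolerance = 1e-9)
  x <- c(0.1, 0.3, 0.77)
  expect_equal(logit(x), -logit(1 - x))
  expect_error(logit(1), "0, 1")
  expect_error(logit(0), "0, 1")
})

test_that("AICc arithmetic, small-sample limit and monotonicity", {
  expect_equal(aicc(-390, 10, 200), 780 + 20 + 220 / 189, tolerance = 1e-12)
  expect_lt(abs(aicc(-100, 3, 1e6) - (200 + 6)), 0.01)
  n <- c(20, 50, 100, 1000)
  corr <- vapply(n, function(nn) aicc(-10, 4, nn) - (20 + 8), numeric(1))
  expect_true(all(diff(corr) < 0))
  expect_error(aicc(-10, 5, 6), "n > K")
})

test_that("model selection computes deltas, weights and candidate flags", {
  one <- model_selection(data.frame(terms = "m1", K = 3, AICc = 100))
  expect_equal(one$weight, 1.0)
  two <- model_selection(data.frame(terms = c("best", "global"), K = c(10, 22),
                                    AICc = c(786.06, 807.98)))
  expect_equal(two$delta, c(0, 21.92))
  expect_equal(two$weight[2], exp(-21.92 / 2) / (1 + exp(-21.92 / 2)),
               tolerance = 1e-9)
  expect_lt(two$weight[2], 2e-5)
  expect_equal(two$candidate, c(TRUE, FALSE))
  set.seed(54)
  many <- model_selection(data.frame(terms = letters[1:6], K = 3:8,
                                     AICc = runif(6, 100, 130)))
  expect_equal(sum(many$weight), 1, tolerance = 1e-9)
  # ranking is invariant to a constant shift of all log-likelihoods
  ll <- -runif(6, 50, 60); K <- 3:8; n <- 40
  a1 <- model_selection(data.frame(terms = letters[1:6], K = K,
                                   AICc = vapply(seq_len(6), function(i)
                                     aicc(ll[i], K[i], n), 1)))
  a2 <- model_selection(data.frame(terms = letters[1:6], K = K,
                                   AICc = vapply(seq_len(6), function(i)
                                     aicc(ll[i] + 13.7, K[i], n), 1)))
  expect_equal(a1$terms, a2$terms)
  expect_equal(a1$delta, a2$delta, tolerance = 1e-9)
})
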