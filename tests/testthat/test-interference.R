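test_that("frequency tables are normalized and Poisson at nu = 1", {
  tab <- build_frequency_tables(1, 100, n_segments = 40000, seed = 3)
  expect_equal(sum(tab$f_nr), 1, tolerance = 1e-9)
  expect_equal(sum(tab$f_sco), 1, tolerance = 1e-9)
  expect_equal(sum(tab$f_dco), 1, tolerance = 1e-9)
  lam <- 1   # 100 cM = 1 Morgan
  for (i in 0:3) {
    p <- dpois(i, lam)
    se <- sqrt(p * (1 - p) / tab$n_segments)
    expect_lt(abs(tab$f_nr[i + 1] - p), 4 * se)
  }
  expect_error(build_frequency_tables(1, 3, bin = 5), "bin")
})

test_that("variance of the count distribution falls as nu rises", {
  vs <- vapply(c(1, 3, 8), function(nu) {
    tab <- build_frequency_tables(nu, 150, n_segments = 30000, seed = 5)
    i <- seq_along(tab$f_nr) - 1
    sum(i^2 * tab$f_nr) - sum(i * tab$f_nr)^2
  }, 1)
  expect_true(all(diff(vs) < 0))
})

test_that("composite likelihood components follow the gamete partition", {
  tab <- build_frequency_tables(2, 100, n_segments = 20000, seed = 7)
  empty <- composite_loglik(list(counts = integer(0), sco = numeric(0),
                                 dco = numeric(0), tco = numeric(0)), tab)
  expect_equal(empty$total, 0)
  ## a 5-CO gamete contributes only through the count component
  obs5 <- list(counts = c(0, 0, 0, 0, 0, 1), sco = numeric(0),
               dco = numeric(0), tco = numeric(0))
  ll <- composite_loglik(obs5, tab)
  expect_equal(ll$sco, 0); expect_equal(ll$dco, 0); expect_equal(ll$tco, 0)
  expect_equal(ll$total, ll$nr)
  ## smoothing flag fires on impossible categories
  expect_true(composite_loglik(list(counts = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2),
                                    sco = numeric(0), dco = numeric(0),
                                    tco = numeric(0)), tab)$smoothed)
})

test_that("the generating nu maximizes the composite likelihood", {
  obs <- chain_obs(2.6, 100, 10000, seed = 8)
  fit <- estimate_nu(obs, 100, grid = seq(1.8, 3.6, by = 0.1),
                     n_segments = 30000, seed = 12)
  expect_lt(abs(fit$nu_hat[["total"]] - 2.6), 0.31)
  obs1 <- chain_obs(1, 100, 10000, seed = 9)
  fit1 <- estimate_nu(obs1, 100, grid = seq(1, 2.5, by = 0.1),
                      n_segments = 30000, seed = 12)
  expect_lte(fit1$nu_hat[["total"]], 1.3)
})

test_that("GIL standardizes di-CO distances per chromosome", {
  map <- data.frame(chrom = 1, id = paste0("m", 1:11),
                    bp = seq(0, 1e8, by = 1e7), cM = seq(0, 100, by = 10))
  mk_ev <- function(sire, son, mids) data.frame(
    sire = sire, son = son, chrom = 1,
    left_bp = mids - 1e4, right_bp = mids + 1e4)
  ## all distances equal: every normalized value 0
  ev <- rbind(mk_ev("s1", "a", c(1e7, 3e7)), mk_ev("s1", "b", c(2e7, 4e7)),
              mk_ev("s2", "c", c(1e7, 3e7)))
  gil <- gil_phenotype(ev, map, unit = "cM")
  expect_true(all(gil$gil == 0))
  ## two sire classes with different interference separate
  set.seed(44)
  recs <- list()
  for (grp in 1:2) {
    nu <- c(1, 8)[grp]
    cs <- bovrec:::chain_segments(nu, 200, 4000)
    first_of <- cumsum(c(0L, cs$counts))
    i2 <- first_of[which(cs$counts == 2L)]
    d2 <- (cs$within[i2 + 2L] - cs$within[i2 + 1L])[1:150] * 1e6  # cM -> bp at 1cM/Mb
    for (k in seq_along(d2))
      recs[[length(recs) + 1L]] <- mk_ev(sprintf("g%d_s%d", grp, k %% 10),
                                         sprintf("son%d_%d", grp, k),
                                         c(1e7, 1e7 + d2[k]))
  }
  map2 <- data.frame(chrom = 1, id = paste0("m", 1:31),
                     bp = seq(0, 3e8, by = 1e7), cM = seq(0, 300, by = 10))
  gil2 <- gil_phenotype(do.call(rbind, recs), map2, unit = "cM")
  g1 <- gil2$gil[grepl("^g1", gil2$sire)]
  g2 <- gil2$gil[grepl("^g2", gil2$sire)]
  expect_gt(mean(g2), mean(g1))   # stronger interference: larger distances
})
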