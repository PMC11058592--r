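mk_series <- function(vals) {
  tibble::tibble(replica = 1, frame = seq_along(vals), rmsd = vals)
}

test_that("labelling follows argmin-then-threshold with 'other' fallback", {
  lab <- label_states(mk_series(c(0.2, 4.0)), mk_series(c(6.1, 4.0)),
                      mk_series(c(9.4, 4.0)))
  expect_equal(as.character(lab$label), c("closed", "other"))
  # exact three-way tie below the cutoff resolves by the fixed priority
  lab2 <- label_states(mk_series(1.0), mk_series(1.0), mk_series(1.0))
  expect_equal(as.character(lab2$label), "closed")
  # misaligned series abort
  bad <- mk_series(c(1, 2)); bad$frame <- c(1, 3)
  expect_error(label_states(mk_series(c(1, 2)), bad, mk_series(c(1, 2))),
               class = "loopshift_error_misaligned_series")
})

test_that("planted Markov states are recovered at >= 99% accuracy when separation >> noise", {
  sim <- quick_sim(seed = 21, n_replicas = 3, n_frames = 500)
  rs <- lapply(sim$references, function(r) rmsd_series(sim$ensemble, r))
  lab <- label_states(rs$closed, rs$open, rs$wide_open)
  acc <- mean(as.character(lab$label) == as.character(sim$labels$label))
  expect_gte(acc, 0.99)
  # winning RMSD of every labelled frame respects its cutoff
  th <- attr(lab, "thresholds_used")
  sub <- lab[lab$label != "other", ]
  win <- cbind(sub$rmsd_closed, sub$rmsd_open, sub$rmsd_wide_open)[
    cbind(seq_len(nrow(sub)), as.integer(sub$label))]
  expect_true(all(win <= th[as.character(sub$label)]))
})

test_that("histograms anchor at zero, conserve counts, use uniform bins", {
  set.seed(31)
  x <- abs(rnorm(75000, 1.5, 0.8))
  h <- rmsd_histogram(x, bin_width = 0.16)
  expect_equal(sum(h$count), 75000)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_equal(h$bin_lo[1], 0)
  expect_equal(unique(round(diff(h$bin_lo), 12)), 0.16)
  # single value occupies the first bin
  h0 <- rmsd_histogram(0.0, bin_width = 0.16)
  expect_equal(h0$count, 1L)
  expect_equal(h0$bin_lo[1], 0)
  # uniform series on [0, 8): each of the 50 bins within binomial 99% CI
  u <- runif(50000, 0, 8)
  hu <- rmsd_histogram(u, bin_width = 0.16)
  expect_equal(nrow(hu), 50)
  ci <- qbinom(c(0.005, 0.995), 50000, 1 / 50)
  expect_true(all(hu$count >= ci[1] & hu$count <= ci[2]))
  expect_error(rmsd_histogram(numeric(0)), class = "loopshift_error_empty_series")
})

test_that("fraction_below is inclusive, reports per replica and pooled, and is monotone", {
  expect_equal(fraction_below(c(1.0, 1.4, 1.6, 2.1), 1.5), 0.5)
  expect_equal(fraction_below(c(1.0, 1.5, 2.0), 1.5), 2 / 3)  # inclusive
  expect_equal(fraction_below(c(3, 1, 2), 3), 1.0)
  tab <- tibble::tibble(replica = rep(1:2, each = 3), frame = rep(1:3, 2),
                        rmsd = c(1, 1, 9, 9, 9, 1))
  fb <- fraction_below(tab, 1.5)
  expect_equal(fb$fraction[fb$replica == "1"], 2 / 3)
  expect_equal(fb$fraction[fb$replica == "pooled"], 0.5)
  # monotone in the cutoff, against an explicit sort-and-count oracle
  set.seed(41)
  for (i in 1:20) {
    x <- rexp(200, 1)
    fr <- vapply(c(1.0, 1.5, 2.0), function(cut) fraction_below(x, cut), numeric(1))
    oracle <- vapply(c(1.0, 1.5, 2.0),
                     function(cut) sum(sort(x) <= cut) / length(x), numeric(1))
    expect_equal(fr, oracle)
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("state populations sum to one, match planted per-replica fractions exactly", {
  lab <- tibble::tibble(
    replica = rep(1:2, each = 10), frame = rep(1:10, 2),
    label = c(rep("wide_open", 7), rep("closed", 3),
              rep("wide_open", 3), rep("closed", 7)))
  pops <- state_populations(lab)
  expect_equal(sum(pops$pooled_fraction), 1, tolerance = 1e-12)
  expect_equal(pops$pooled_fraction[pops$state == "wide_open"], 0.5)
  per <- tidy(pops)
  expect_equal(per$fraction[per$replica == 1 & per$state == "wide_open"], 0.7)
  expect_equal(per$fraction[per$replica == 2 & per$state == "wide_open"], 0.3)
  # all-closed degenerate case
  all_closed <- tibble::tibble(replica = 1, frame = 1:5, label = "closed")
  p2 <- state_populations(all_closed)
  expect_equal(p2$pooled_fraction, c(1, 0, 0, 0))
  expect_equal(p2$se, rep(0, 4))
})

test_that("pooled populations of a Markov ensemble sit within 3 SE of the eigen stationary law", {
  P <- stationary_transition_matrix(c(0.2, 0.3, 0.5), mixing = 0.2)
  pi_star <- stationary_distribution(P)
  expect_equal(unname(pi_star), c(0.2, 0.3, 0.5), tolerance = 1e-12)
  sim <- quick_sim(seed = 51, n_replicas = 6, n_frames = 800,
                   transition_matrix = P)
  pops <- state_populations(sim$labels)
  for (s in c("closed", "open", "wide_open")) {
    row <- pops[pops$state == s, ]
    expect_lt(abs(row$pooled_fraction - pi_star[s]), 3 * max(row$se, 1e-3))
  }
})

test_that("label-based populations never exceed the plain cutoff fraction", {
  sim <- quick_sim(seed = 61, n_replicas = 2, n_frames = 300)
  rs <- lapply(sim$references, function(r) rmsd_series(sim$ensemble, r))
  lab <- label_states(rs$closed, rs$open, rs$wide_open)
  pops <- state_populations(lab)
  frac <- fraction_below(rs$closed$rmsd, 1.5)
  expect_lte(pops$pooled_fraction[pops$state == "closed"], frac + 1e-12)
})

test_that("closure analysis applies terminal-window means and joint cutoffs", {
  rmsd <- tibble::tibble(replica = rep(1:3, each = 10), frame = rep(1:10, 3),
                         rmsd = c(rep(3, 5), rep(1.0, 5),
                                  rep(3, 5), rep(1.0, 5),
                                  rep(3, 5), rep(3.0, 5)))
  dist <- tibble::tibble(replica = rep(1:3, each = 10), frame = rep(1:10, 3),
                         dist = c(rep(9, 5), rep(4.0, 5),
                                  rep(9, 5), rep(7.0, 5),
                                  rep(9, 5), rep(7.0, 5)))
  out <- closure_analysis(rmsd, dist, window = 5, rmsd_cut = 1.5, dist_cut = 5)
  expect_equal(out$mean_rmsd, c(1, 1, 3))
  expect_equal(out$mean_dist, c(4, 7, 7))
  expect_equal(out$closed, c(TRUE, TRUE, FALSE))
  expect_equal(out$productive, c(TRUE, FALSE, FALSE))
  # window = n_frames covers the whole trajectory without error
  whole <- closure_analysis(rmsd, dist, window = 10, rmsd_cut = 1.5, dist_cut = 5)
  expect_equal(whole$mean_rmsd, c(2, 2, 3))
  expect_error(closure_analysis(rmsd, dist, window = 11, rmsd_cut = 1.5,
                                dist_cut = 5),
               class = "loopshift_error_bad_window")
})

test_that("closure planted only in productive replicas yields an empty closed-and-non-productive cell", {
  set.seed(71)
  n_rep <- 12
  productive <- rep(c(TRUE, FALSE), each = n_rep / 2)
  rmsd <- purrr::map_dfr(seq_len(n_rep), function(r) {
    base <- if (productive[r]) 0.9 else 3.5
    tibble::tibble(replica = r, frame = 1:50, rmsd = abs(rnorm(50, base, 0.1)))
  })
  dist <- purrr::map_dfr(seq_len(n_rep), function(r) {
    base <- if (productive[r]) 4.0 else 8.0
    tibble::tibble(replica = r, frame = 1:50, dist = abs(rnorm(50, base, 0.2)))
  })
  out <- closure_analysis(rmsd, dist, window = 25, rmsd_cut = 1.5, dist_cut = 5)
  expect_equal(sum(out$closed & !out$productive), 0)
  expect_gt(sum(out$closed & out$productive), 0)
})
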