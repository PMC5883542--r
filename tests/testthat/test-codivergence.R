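test_that("summary statistics match hand counts", {
  # all identical: every statistic zero
  same <- matrix("A", 2, 100)
  s0 <- summary_stats(list(a = same, b = same))
  expect_equal(unname(s0[c("pi_between", "pi_within_mean", "theta_w_a",
                           "theta_w_b", "pi_net")]), rep(0, 5))

  # side a: two sequences differing at 4 of 100 sites
  a1 <- rep("A", 100); a2 <- a1; a2[1:4] <- "G"
  s <- summary_stats(list(a = rbind(a1, a2), b = same))
  expect_equal(unname(s["pi_within_a"]), 0.04)
  expect_equal(unname(s["theta_w_a"]), 0.04)   # a_2 = 1
  expect_equal(unname(s["S_a"]), 4)
  expect_equal(unname(s["pi_within_b"]), 0)
})

test_that("fixed between-side differences move pi_b and pi_net equally", {
  set.seed(2)
  a <- random_alignment(3, 200, paste0("a", 1:3))
  b <- a[c(1, 2, 3), ]; rownames(b) <- paste0("b", 1:3)
  b[, 1:10] <- "A"; a[, 1:10] <- "A"
  s1 <- summary_stats(list(a = a, b = b))
  # introduce 8 fixed differences between the sides
  b2 <- b; b2[, 1:8] <- "G"
  s2 <- summary_stats(list(a = a, b = b2))
  expect_equal(s2[["pi_between"]] - s1[["pi_between"]], 8 / 200)
  expect_equal(s2[["pi_net"]] - s1[["pi_net"]], 8 / 200)
  expect_equal(s2[["pi_within_mean"]], s1[["pi_within_mean"]])
})

test_that("the pair simulator honours its contracts", {
  expect_error(simulate_pair(0, 0.01, 0.01, 0.1, 4, 4, 100), "thetas")
  expect_error(simulate_pair(0.01, 0.01, 0.01, -1, 4, 4, 100), "tau")

  # determinism under a fixed seed
  p1 <- simulate_pair(0.01, 0.01, 0.01, 0.1, 4, 4, 394, seed = 5)
  p2 <- simulate_pair(0.01, 0.01, 0.01, 0.1, 4, 4, 394, seed = 5)
  expect_identical(p1, p2)
  expect_equal(dim(p1$a), c(4, 394))

  # deep split: pi_b exceeds pi_w in nearly every replicate at tau = 10 theta
  set.seed(77)
  wins <- 0L
  for (r in 1:200) {
    p <- simulate_pair(0.01, 0.01, 0.01, 0.1, 3, 3, 394)
    s <- summary_stats(p)
    if (s[["pi_between"]] > s[["pi_within_mean"]]) wins <- wins + 1L
  }
  expect_gte(wins / 200, 0.95)
})

test_that("tau = 0 with equal thetas collapses to one panmictic population", {
  set.seed(88)
  diffs <- vapply(1:500, function(r) {
    p <- simulate_pair(0.01, 0.01, 0.01, 0, 3, 3, 394)
    s <- summary_stats(p)
    s[["pi_between"]] - s[["pi_within_mean"]]
  }, numeric(1))
  # E[pi_b - pi_w] = 0; the mean must sit within Monte-Carlo error
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)))
})

test_that("the DP hyperprior is calibrated to the scenario mean", {
  expect_error(calibrate_dp_scale(6, 0.5), "must lie")
  expect_error(calibrate_dp_scale(6, 7), "must lie")
  pairs <- paste0("p", 1:6)
  for (target in c(2, 4, 6)) {
    pr <- sample_prior(target, pairs, 1e5, seed = 17)
    eff <- min(target, 6 - 0.15)
    expect_lt(abs(mean(pr$psi) - eff), 0.2)
    # psi always equals the number of distinct event labels
    idx <- sample(1e5, 500)
    expect_equal(pr$psi[idx],
                 apply(pr$assignment[idx, ], 1,
                       function(a) length(unique(a))))
    # taus shared within an event, bounded by tau_max
    expect_true(all(pr$tau_pair >= 0 & pr$tau_pair <= 0.35))
    d <- which(pr$psi == 1)[1]
    expect_equal(length(unique(pr$tau_pair[d, ])), 1L)
  }
  # six-event scenario concentrates on full partitions far more than the
  # two-event scenario
  p2 <- sample_prior(2, pairs, 1e4, seed = 3)
  p6 <- sample_prior(6, pairs, 1e4, seed = 3)
  expect_gt(mean(p6$psi == 6), mean(p2$psi == 6))
})

test_that("constraint probabilities follow their definitions", {
  draws <- list(
    psi = c(1L, 1L, 2L, 2L),
    assignment = rbind(c(1L, 1L, 1L), c(1L, 1L, 1L),
                       c(1L, 2L, 1L), c(1L, 1L, 2L)),
    tau_pair = rbind(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1),
                     c(0.3, 0.1, 0.3), c(0.2, 0.2, 0.1)),
    n_draws = 4L)
  colnames(draws$assignment) <- colnames(draws$tau_pair) <- c("x", "y", "z")
  expect_equal(constraint_probability(draws, sync_model(c("x", "y", "z"))),
               0.5)
  expect_equal(constraint_probability(draws, sync_model(c("x", "z"))), 0.75)
  # BEFORE({x}, {y}): tau_x > tau_y in exactly draw 3 -> 0.25; and the
  # hand-built case with 2 of 4 satisfying
  expect_equal(constraint_probability(draws, before_model("x", "y")), 0.25)
  expect_equal(constraint_probability(draws, before_model(c("x", "y"), "z")),
               0.25)
  expect_error(constraint_probability(draws, sync_model("nope")),
               "unknown pair id")
  expect_error(sync_model(character(0)), "empty")
  expect_error(before_model("x", character(0)), "empty")

  # all draws synchronous
  all_sync <- list(psi = c(1L, 1L),
                   assignment = rbind(c(1L, 1L), c(1L, 1L)),
                   tau_pair = rbind(c(0.1, 0.1), c(0.2, 0.2)),
                   n_draws = 2L)
  colnames(all_sync$assignment) <- colnames(all_sync$tau_pair) <- c("x", "y")
  expect_equal(constraint_probability(all_sync, sync_model(c("x", "y"))), 1)
})

test_that("prior synchrony is likelier under fewer divergence events", {
  pairs <- six_pair_table()
  m <- guild_models(pairs)$all_synchronised
  p2 <- constraint_probability(sample_prior(2, pairs, 1e5, seed = 5), m)
  p6 <- constraint_probability(sample_prior(6, pairs, 1e5, seed = 5), m)
  expect_gt(p2, p6)
})

test_that("the nine guild models are built from the pair table", {
  m <- guild_models(six_pair_table())
  expect_length(m, 9)
  expect_setequal(m$all_synchronised$set,
                  c("Eupristina", "Walkerella", "Philotrypesis",
                    "Sycoscapter", "Sycobia", "Sycophila"))
  expect_setequal(m$gallers_before_parasitoids$set1,
                  c("Eupristina", "Walkerella", "Sycobia"))
  expect_setequal(m$gallers_before_parasitoids$set2,
                  c("Philotrypesis", "Sycoscapter", "Sycophila"))
  expect_setequal(m$large_synchronised$set, c("Sycobia", "Sycophila"))
  expect_equal(m$pollinators_before_small_parasitoids$set1, "Eupristina")
})

test_that("Bayes factors follow the odds-ratio definition and Raftery scale", {
  b <- bayes_factor(0.3, 0.3)
  expect_equal(b$BF, 1)
  expect_equal(b$two_ln_BF, 0)
  expect_equal(b$raftery_category, "none")

  expect_equal(bayes_factor(0.814, 0.582)$BF,
               (0.814 / 0.186) / (0.582 / 0.418))
  # category boundaries on 2 ln BF
  bf_at <- function(two_ln) {
    q <- 0.5
    p <- 1 / (1 + (1 - q) / q / exp(two_ln / 2))
    bayes_factor(p, q)$raftery_category
  }
  expect_equal(bf_at(1.9), "none")
  expect_equal(bf_at(2.1), "positive")
  expect_equal(bf_at(5.5), "strong")
  expect_equal(bf_at(10.5), "very_strong")

  # degenerate probabilities
  z <- bayes_factor(0, 0.5)
  expect_equal(z$BF, 0)
  expect_equal(z$two_ln_BF, -Inf)
  inf <- bayes_factor(0.2, 0)
  expect_equal(inf$raftery_category, "infinite")
  expect_error(bayes_factor(1.2, 0.5), "0, 1")
  expect_error(bayes_factor(0.5, 1), "< 1")
})

test_that("rejection sampling is deterministic and recovers the truth", {
  pairs <- six_pair_table()
  obs <- observed_pairs(rep(0.0988, 6), seed = 7)
  post1 <- habc_reject(obs, pairs, 2, n_sims = 10000, keep_fraction = 0.01,
                       seed = 19)
  post2 <- habc_reject(obs, pairs, 2, n_sims = 10000, keep_fraction = 0.01,
                       seed = 19)
  expect_identical(post1$retained, post2$retained)
  expect_identical(post1$distances, post2$distances)
  expect_equal(post1$retained$n_draws, 100)
  expect_true(all(diff(post1$distances) >= 0))

  # parameter recovery: the generating mean tau lies within one posterior
  # SD of the retained mean
  mean_tau <- rowMeans(post1$retained$tau_pair)
  expect_lt(abs(mean(mean_tau) - 0.0988), sd(mean_tau) + 1e-12)
})

test_that("keeping every draw returns the prior (no-data limit)", {
  pairs <- six_pair_table()
  obs <- observed_pairs(rep(0.1, 6), seed = 23)
  post <- habc_reject(obs, pairs, 2, n_sims = 10000, keep_fraction = 1,
                      seed = 29)
  expect_equal(post$retained$n_draws, 10000)
  fresh <- sample_prior(2, pairs, 10000, seed = 31)
  tab_post <- table(factor(pmin(post$retained$psi, 6), levels = 1:6))
  tab_fresh <- table(factor(pmin(fresh$psi, 6), levels = 1:6))
  keep <- tab_post + tab_fresh > 0
  test <- suppressWarnings(
    stats::chisq.test(rbind(tab_post[keep], tab_fresh[keep])))
  expect_gt(test$p.value, 0.01)
})

test_that("posterior mean divergence time converts tau through the clock", {
  draws <- list(psi = rep(1L, 3),
                assignment = matrix(1L, 3, 6),
                tau_pair = matrix(0.0988, 3, 6),
                n_draws = 3L)
  colnames(draws$tau_pair) <- paste0("p", 1:6)
  est <- mean_divergence_time(draws, clock_rate = 0.019)
  expect_equal(est$estimate_Ma, 5.2)
  expect_equal(est$sd_Ma, 0)
  # doubling the clock rate halves the estimate
  est2 <- mean_divergence_time(draws, clock_rate = 0.038)
  expect_equal(est2$estimate_Ma, 2.6)
  expect_error(mean_divergence_time(draws, clock_rate = 0), "> 0")
})

test_that("model evaluation tabulates posterior, prior and Bayes factor", {
  pairs <- six_pair_table()
  obs <- observed_pairs(rep(0.0988, 6), seed = 37)
  post <- habc_reject(obs, pairs, 2, n_sims = 4000, keep_fraction = 0.02,
                      seed = 41)
  tab <- evaluate_guild_models(post, n_prior_draws = 5000, seed = 43)
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$posterior_p >= 0 & tab$posterior_p <= 1))
  expect_true(all(tab$prior_p >= 0 & tab$prior_p < 1))
  finite <- is.finite(tab$BF) & tab$posterior_p > 0
  odds <- function(p) p / (1 - p)
  expect_equal(tab$BF[finite],
               odds(tab$posterior_p[finite]) / odds(tab$prior_p[finite]))
})
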