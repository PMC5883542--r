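# Hierarchical ABC test of guild-clustered intercontinental divergence:
# isolation-coalescent simulator, summary statistics, Dirichlet-process
# prior over divergence events, rejection sampling, constraint
# probabilities and Bayes factors.

int_to_base <- function(m) {
  out <- matrix(.BASES[m + 1L], nrow(m), ncol(m))
  rownames(out) <- rownames(m)
  out
}

#' Simulate a sister-species pair under the isolation coalescent
#'
#' Standard two-population isolation model: lineages coalesce within each
#' descendant population at the rate set by its theta, merge into the
#' ancestral population at the split, and coalesce there under
#' `theta_anc`.  Mutations follow a Poisson process along branches with
#' Jukes-Cantor substitution.  Time units are expected pairwise
#' substitutions per site, so the split lies `tau / 2` lineage-units in
#' the past and the expected raw between-population divergence is
#' approximately `tau + theta_anc`.
#'
#' @param theta_a,theta_b,theta_anc population mutation parameters
#'   (4N mu per site) for the two descendants and the ancestor; all > 0.
#' @param tau divergence time in expected pairwise substitutions/site
#'   (>= 0).
#' @param n_a,n_b sample sizes per side (>= 2 each for the hABC).
#' @param L alignment length in bp.
#' @param seed optional integer seed; a fixed seed reproduces the
#'   alignment exactly.
#' @return List of class `pair_alignment` with character matrices `a`
#'   and `b` (rows = sequences) and element `L`.
#' @export
simulate_pair <- function(theta_a, theta_b, theta_anc, tau, n_a, n_b, L,
                          seed = NULL) {
  if (any(c(theta_a, theta_b, theta_anc) <= 0) || tau < 0 || L < 1 ||
      n_a < 1 || n_b < 1)
    stop("thetas must be > 0, tau >= 0, n_a/n_b/L >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- .sim_isolation_pair_cpp(theta_a, theta_b, theta_anc, tau,
                               as.integer(n_a), as.integer(n_b),
                               as.integer(L), -1, NULL)
  rownames(m) <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  seqs <- int_to_base(m)
  structure(list(a = seqs[seq_len(n_a), , drop = FALSE],
                 b = seqs[n_a + seq_len(n_b), , drop = FALSE], L = L),
            class = "pair_alignment")
}

pairwise_pi <- function(x, y = NULL) {
  # mean proportion of differing sites over pairwise-complete columns
  cross <- !is.null(y)
  if (!cross) y <- x
  tot <- 0; np <- 0L
  for (i in seq_len(nrow(x))) {
    jj <- if (cross) seq_len(nrow(y)) else if (i < nrow(x)) (i + 1L):nrow(y) else integer(0)
    for (j in jj) {
      ok <- x[i, ] %in% .BASES & y[j, ] %in% .BASES
      if (!any(ok)) next
      tot <- tot + sum(x[i, ok] != y[j, ok]) / sum(ok)
      np <- np + 1L
    }
  }
  if (np == 0L) stop("no pairwise-complete columns", call. = FALSE)
  tot / np
}

segregating_sites <- function(x) {
  # columns with >= 2 distinct bases, among columns complete in all rows
  complete <- colSums(matrix(x %in% .BASES, nrow(x))) == nrow(x)
  if (!any(complete)) return(c(S = 0L, L_used = 0L))
  xs <- x[, complete, drop = FALSE]
  seg <- vapply(seq_len(ncol(xs)), function(s) length(unique(xs[, s])) > 1L,
                logical(1))
  c(S = sum(seg), L_used = ncol(xs))
}

watterson_a <- function(n) if (n < 2) NA_real_ else sum(1 / seq_len(n - 1))

#' Summary statistics for a sister pair
#'
#' Computes the standard per-pair statistics used by the hABC: mean
#' pairwise diversity between populations (`pi_between`), within each
#' population (`pi_within_a/b`, mean in `pi_within_mean`), Watterson's
#' estimator `theta_W = S / (a_n L)` per population, segregating sites,
#' and net divergence `pi_net = pi_between - pi_within_mean`.
#'
#' @param pair a `pair_alignment` (see [simulate_pair()]) or a list with
#'   character matrices `a` and `b`.
#' @return Named numeric vector: `pi_between`, `pi_within_a`,
#'   `pi_within_b`, `pi_within_mean`, `theta_w_a`, `theta_w_b`, `S_a`,
#'   `S_b`, `pi_net`.
#' @export
summary_stats <- function(pair) {
  a <- pair$a; b <- pair$b
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("need >= 2 sequences per side", call. = FALSE)
  pi_b <- pairwise_pi(a, b)
  pi_a <- pairwise_pi(a)
  pi_bb <- pairwise_pi(b)
  sa <- segregating_sites(a)
  sb <- segregating_sites(b)
  if (sa["L_used"] == 0L && sb["L_used"] == 0L)
    stop("all sites invalid", call. = FALSE)
  th_a <- unname(sa["S"] / (watterson_a(nrow(a)) * max(sa["L_used"], 1L)))
  th_b <- unname(sb["S"] / (watterson_a(nrow(b)) * max(sb["L_used"], 1L)))
  piw <- 0.5 * (pi_a + pi_bb)
  c(pi_between = pi_b, pi_within_a = pi_a, pi_within_b = pi_bb,
    pi_within_mean = piw, theta_w_a = th_a, theta_w_b = th_b,
    S_a = unname(sa["S"]), S_b = unname(sb["S"]), pi_net = pi_b - piw)
}

# the six per-pair statistics entering the ABC distance, in the order
# produced by the C++ batch simulator
.ABC_STATS <- c("pi_between", "pi_within_a", "pi_within_b",
                "theta_w_a", "theta_w_b", "pi_net")

abc_stat_vector <- function(stats) unname(stats[.ABC_STATS])

# ---- Dirichlet-process prior over divergence events ----------------------

# E[number of CRP categories] for n customers at concentration alpha
crp_expected_k <- function(alpha, n) {
  vapply(alpha, function(a) sum(a / (a + 0:(n - 1))), numeric(1))
}

# E over alpha ~ Gamma(shape, scale) of the expected category count;
# substituting alpha = scale * x keeps the integrand well scaled for any
# concentration
dp_expected_psi <- function(scale, n, shape = 2) {
  1 + sum(vapply(seq_len(n - 1), function(i) {
    stats::integrate(function(x) scale * x / (scale * x + i) *
                       dgamma(x, shape = shape, rate = 1),
                     0, Inf, rel.tol = 1e-9)$value
  }, numeric(1)))
}

.dp_scale_cache <- new.env(parent = emptyenv())

#' Calibrate the Dirichlet-process concentration hyperprior
#'
#' The divergence-scenario label (two, four or six events) is read as the
#' prior mean of the number of divergence events Psi.  The concentration
#' alpha carries a diffuse Gamma(shape 2) hyperprior whose scale is
#' solved numerically so that `E[Psi]` matches the target.  Because a
#' finite concentration always gives `E[Psi]` strictly below the number of
#' pairs, a target equal to the number of pairs is moved to
#' `n_pairs - 0.15`.
#'
#' @param n_pairs number of sister pairs.
#' @param target_psi prior mean number of divergence events.
#' @param shape Gamma shape of the hyperprior (default 2).
#' @return The Gamma scale (numeric scalar).
#' @export
calibrate_dp_scale <- function(n_pairs, target_psi, shape = 2) {
  if (target_psi < 1 || target_psi > n_pairs)
    stop("target_psi must lie in [1, n_pairs]", call. = FALSE)
  eff <- min(target_psi, n_pairs - 0.15)
  key <- paste(n_pairs, eff, shape)
  if (!is.null(.dp_scale_cache[[key]])) return(.dp_scale_cache[[key]])
  f <- function(s) dp_expected_psi(s, n_pairs, shape) - eff
  s <- uniroot(f, lower = 1e-4, upper = 1e6, tol = 1e-8)$root
  .dp_scale_cache[[key]] <- s
  s
}

crp_partition <- function(alpha, n) {
  # Chinese-restaurant-process seating; returns event index per pair
  assign <- integer(n)
  counts <- integer(0)
  assign[1] <- 1L; counts <- 1L
  if (n > 1) for (j in 2:n) {
    p_new <- alpha / (alpha + j - 1)
    if (runif(1) < p_new) {
      counts <- c(counts, 1L)
      assign[j] <- length(counts)
    } else {
      k <- sample.int(length(counts), 1, prob = counts)
      counts[k] <- counts[k] + 1L
      assign[j] <- k
    }
  }
  assign
}

#' Draw from the hierarchical prior over divergence histories
#'
#' Each draw consists of a partition of the sister pairs into divergence
#' events (Chinese restaurant process with concentration alpha ~
#' Gamma(2, scale) calibrated by scenario), one divergence time tau ~
#' Uniform(0, tau_max) per event (expected pairwise substitutions per
#' site), and independent Uniform(0, theta_max) population mutation
#' parameters for each descendant and ancestral population of each pair.
#'
#' @param scenario prior mean number of divergence events (the published analysis's
#'   two-, four- and six-divergence scenarios; any value in
#'   `[1, n_pairs]` accepted).
#' @param pairs data.frame with columns `pair_id` and `guild` (one row
#'   per sister pair), or a character vector of pair ids.
#' @param n_draws number of draws.
#' @param seed optional integer seed.
#' @param tau_max upper bound of the uniform tau prior (default 0.35,
#'   about 18 Ma at the 1.9% pairwise/Myr clock).
#' @param theta_max upper bound of the uniform theta priors
#'   (default 0.02).
#' @return List of class `prior_draws`: `psi` (integer vector),
#'   `assignment` and `tau_pair` (n_draws x n_pairs matrices),
#'   `theta_a`, `theta_b`, `theta_anc` (same shape), `alpha`, plus the
#'   settings.
#' @export
sample_prior <- function(scenario, pairs, n_draws, seed = NULL,
                         tau_max = 0.35, theta_max = 0.02) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (is.character(pairs)) pairs <- data.frame(pair_id = pairs,
                                               guild = NA_character_)
  n_pairs <- nrow(pairs)
  if (n_pairs < 1) stop("empty pair list", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  scale <- calibrate_dp_scale(n_pairs, scenario)
  alpha <- rgamma(n_draws, shape = 2, scale = scale)
  assignment <- matrix(0L, n_draws, n_pairs,
                       dimnames = list(NULL, pairs$pair_id))
  tau_pair <- matrix(0, n_draws, n_pairs,
                     dimnames = list(NULL, pairs$pair_id))
  psi <- integer(n_draws)
  for (d in seq_len(n_draws)) {
    a <- crp_partition(alpha[d], n_pairs)
    k <- max(a)
    taus <- runif(k, 0, tau_max)
    assignment[d, ] <- a
    tau_pair[d, ] <- taus[a]
    psi[d] <- k
  }
  th <- function() matrix(runif(n_draws * n_pairs, 0, theta_max),
                          n_draws, n_pairs,
                          dimnames = list(NULL, pairs$pair_id))
  structure(list(psi = psi, assignment = assignment, tau_pair = tau_pair,
                 theta_a = th(), theta_b = th(), theta_anc = th(),
                 alpha = alpha, pairs = pairs, scenario = scenario,
                 tau_max = tau_max, theta_max = theta_max,
                 n_draws = n_draws),
            class = "prior_draws")
}

#' @export
print.prior_draws <- function(x, ...) {
  cat("<prior_draws> ", x$n_draws, " draws over ", nrow(x$pairs),
      " pairs; scenario E[Psi] target ", x$scenario,
      "; mean Psi ", round(mean(x$psi), 3), "\n", sep = "")
  invisible(x)
}

subset_draws <- function(draws, idx) {
  draws$psi <- draws$psi[idx]
  for (f in c("assignment", "tau_pair", "theta_a", "theta_b", "theta_anc"))
    draws[[f]] <- draws[[f]][idx, , drop = FALSE]
  draws$alpha <- draws$alpha[idx]
  draws$n_draws <- length(idx)
  draws
}

#' hABC rejection sampling
#'
#' Simulates every prior draw through the isolation coalescent, computes
#' the six per-pair summary statistics, standardizes each statistic by
#' the simulated pool's mean and standard deviation, and retains the
#' `keep_fraction` of draws closest to the observed statistics in
#' Euclidean distance.  Statistics with zero variance in the pool are
#' dropped with a warning.
#'
#' @param observed either a list of per-pair statistic vectors from
#'   [summary_stats()] (in pair order) or a list of `pair_alignment`
#'   objects.
#' @param pairs data.frame with columns `pair_id`, `guild`, `n_a`, `n_b`
#'   (sample sizes per side).
#' @param scenario prior mean number of divergence events.
#' @param n_sims number of prior simulations (>= 1000 recommended; a
#'   warning is issued below that).
#' @param keep_fraction fraction of closest draws retained
#'   (default 0.01).
#' @param seed optional integer seed.
#' @param L alignment length simulated (default 394 bp).
#' @param tau_max,theta_max prior bounds, as in [sample_prior()].
#' @return List of class `habc_posterior`: `retained` (a `prior_draws`
#'   subset with distances ascending), `distances`, `prior` (the full
#'   prior draws), `dropped_stats`, and the settings.
#' @export
habc_reject <- function(observed, pairs, scenario, n_sims,
                        keep_fraction = 0.01, seed = NULL, L = 394,
                        tau_max = 0.35, theta_max = 0.02) {
  if (nrow(pairs) < 2L) stop("need >= 2 pairs", call. = FALSE)
  if (n_sims < 1000) warning("n_sims < 1000 gives unreliable posteriors")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  obs_vec <- unlist(lapply(observed, function(o) {
    if (inherits(o, "pair_alignment") || (is.list(o) && !is.null(o$a)))
      o <- summary_stats(o)
    abc_stat_vector(o)
  }))
  if (length(obs_vec) != 6L * nrow(pairs))
    stop("observed statistics do not match the pair table", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prior <- sample_prior(scenario, pairs, n_sims, seed = NULL,
                        tau_max = tau_max, theta_max = theta_max)
  sims <- .habc_sim_stats_cpp(prior$tau_pair, prior$theta_a, prior$theta_b,
                              prior$theta_anc,
                              as.integer(pairs$n_a), as.integer(pairs$n_b),
                              as.integer(L))
  mu <- colMeans(sims)
  sdev <- apply(sims, 2, sd)
  keep_cols <- sdev > 0
  dropped <- which(!keep_cols)
  if (length(dropped))
    warning(length(dropped), " zero-variance statistic(s) dropped")
  z_sims <- sweep(sweep(sims[, keep_cols, drop = FALSE], 2, mu[keep_cols]),
                  2, sdev[keep_cols], "/")
  z_obs <- (obs_vec[keep_cols] - mu[keep_cols]) / sdev[keep_cols]
  dist <- sqrt(rowSums(sweep(z_sims, 2, z_obs)^2))
  k <- max(1L, floor(keep_fraction * n_sims))
  ord <- order(dist)[seq_len(k)]
  structure(list(retained = subset_draws(prior, ord),
                 distances = dist[ord],
                 prior = prior,
                 dropped_stats = dropped,
                 keep_fraction = keep_fraction, n_sims = n_sims,
                 L = L, scenario = scenario, observed = obs_vec),
            class = "habc_posterior")
}

#' @export
print.habc_posterior <- function(x, ...) {
  cat("<habc_posterior> ", x$retained$n_draws, "/", x$n_sims,
      " draws retained (keep ", x$keep_fraction, "); scenario ",
      x$scenario, "\n  posterior mean Psi ",
      round(mean(x$retained$psi), 3), "\n", sep = "")
  invisible(x)
}

# ---- guild models and Bayes factors --------------------------------------

#' Constraint models of guild-staggered divergence
#'
#' `sync_model(set)` holds when every pair in `set` shares one divergence
#' event; `before_model(set1, set2)` holds when every pair in `set1`
#' diverged strictly earlier (larger tau) than every pair in `set2`.
#'
#' @param name model label.
#' @param set,set1,set2 character vectors of pair ids.
#' @return A `guild_model` list with `name`, `type` and the sets.
#' @export
sync_model <- function(set, name = "sync") {
  if (!length(set)) stop("empty set in SYNC model", call. = FALSE)
  structure(list(name = name, type = "SYNC", set = set),
            class = "guild_model")
}

#' @rdname sync_model
#' @export
before_model <- function(set1, set2, name = "before") {
  if (!length(set1) || !length(set2))
    stop("empty set in BEFORE model", call. = FALSE)
  structure(list(name = name, type = "BEFORE", set1 = set1, set2 = set2),
            class = "guild_model")
}

#' The nine guild divergence models
#'
#' Builds the nine evaluated hypotheses of guild-clustered divergence
#' from a pair table: all pairs synchronous; gallers (pollinator + small
#' + large gallers) before parasitoids; small wasps before large; small
#' wasps synchronous; small gallers before small parasitoids;
#' pollinators synchronous with small parasitoids; pollinators before
#' small parasitoids; large wasps synchronous; large gallers before
#' large parasitoids.  Models whose guild sets are empty for the given
#' pair table are omitted.
#'
#' @param pairs data.frame with columns `pair_id` and `guild`.
#' @return Named list of `guild_model` objects.
#' @export
guild_models <- function(pairs) {
  of <- function(g) pairs$pair_id[pairs$guild %in% g]
  poll <- of("pollinator"); sg <- of("small_galler")
  sp <- of("small_parasitoid"); lg <- of("large_galler")
  lp <- of("large_parasitoid")
  small <- c(poll, sg, sp); large <- c(lg, lp)
  gallers <- c(poll, sg, lg); parasitoids <- c(sp, lp)
  candidates <- list(
    all_synchronised = list("SYNC", pairs$pair_id),
    gallers_before_parasitoids = list("BEFORE", gallers, parasitoids),
    small_before_large = list("BEFORE", small, large),
    small_synchronised = list("SYNC", small),
    small_gallers_before_small_parasitoids = list("BEFORE", sg, sp),
    pollinators_sync_small_parasitoids = list("SYNC", c(poll, sp)),
    pollinators_before_small_parasitoids = list("BEFORE", poll, sp),
    large_synchronised = list("SYNC", large),
    large_gallers_before_large_parasitoids = list("BEFORE", lg, lp)
  )
  out <- list()
  for (nm in names(candidates)) {
    cc <- candidates[[nm]]
    if (cc[[1]] == "SYNC") {
      if (length(cc[[2]]) >= 2L) out[[nm]] <- sync_model(cc[[2]], nm)
    } else {
      if (length(cc[[2]]) && length(cc[[3]]))
        out[[nm]] <- before_model(cc[[2]], cc[[3]], nm)
    }
  }
  out
}

#' Fraction of draws satisfying a guild model
#'
#' SYNC: all pairs in the set share one event index.  BEFORE: the
#' youngest tau in the first set is strictly older (larger) than the
#' oldest tau in the second.
#'
#' @param draws a `prior_draws` object or the `retained` component of an
#'   `habc_posterior`.
#' @param model a `guild_model`.
#' @return Probability (numeric scalar).
#' @export
constraint_probability <- function(draws, model) {
  if (inherits(draws, "habc_posterior")) draws <- draws$retained
  if (draws$n_draws == 0L) stop("empty draw collection", call. = FALSE)
  ids <- colnames(draws$assignment)
  if (model$type == "SYNC") {
    cols <- match(model$set, ids)
    if (anyNA(cols)) stop("unknown pair id in model set", call. = FALSE)
    sub <- draws$assignment[, cols, drop = FALSE]
    mean(apply(sub, 1, function(r) length(unique(r)) == 1L))
  } else {
    c1 <- match(model$set1, ids); c2 <- match(model$set2, ids)
    if (anyNA(c1) || anyNA(c2))
      stop("unknown pair id in model set", call. = FALSE)
    t1 <- draws$tau_pair[, c1, drop = FALSE]
    t2 <- draws$tau_pair[, c2, drop = FALSE]
    mean(apply(t1, 1, min) > apply(t2, 1, max))
  }
}

#' Bayes factor on Raftery's scale
#'
#' `BF = [p / (1 - p)] / [q / (1 - q)]` (posterior odds over prior
#' odds), reported with `2 ln BF` and Raftery's category: none below 2,
#' positive in `[2, 5]`, strong in `(5, 10]`, very strong above 10.  A
#' zero posterior gives `BF = 0` with `2 ln BF = -Inf`; a zero prior
#' with positive posterior is the infinite-support category.
#'
#' @param posterior_p,prior_p probabilities in `[0, 1]`; `prior_p < 1`.
#' @return List of class `bayes_factor`: `posterior_p`, `prior_p`, `BF`,
#'   `two_ln_BF`, `raftery_category`.
#' @export
bayes_factor <- function(posterior_p, prior_p) {
  if (posterior_p < 0 || posterior_p > 1 || prior_p < 0 || prior_p > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (prior_p >= 1) stop("prior_p must be < 1", call. = FALSE)
  if (prior_p == 0) {
    if (posterior_p > 0)
      return(structure(list(posterior_p = posterior_p, prior_p = prior_p,
                            BF = Inf, two_ln_BF = Inf,
                            raftery_category = "infinite"),
                       class = "bayes_factor"))
    return(structure(list(posterior_p = 0, prior_p = 0, BF = NA_real_,
                          two_ln_BF = NA_real_, raftery_category = "none"),
                     class = "bayes_factor"))
  }
  bf <- (posterior_p / (1 - posterior_p)) / (prior_p / (1 - prior_p))
  two_ln <- 2 * log(bf)
  cat_ <- if (!is.finite(two_ln) && two_ln < 0) "none"
          else if (two_ln < 2) "none"
          else if (two_ln <= 5) "positive"
          else if (two_ln <= 10) "strong"
          else "very_strong"
  structure(list(posterior_p = posterior_p, prior_p = prior_p, BF = bf,
                 two_ln_BF = two_ln, raftery_category = cat_),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat("BF = ", format(x$BF, digits = 4), " (2lnBF = ",
      format(x$two_ln_BF, digits = 4), "; ", x$raftery_category,
      ")  posterior ", x$posterior_p, " vs prior ", x$prior_p, "\n",
      sep = "")
  invisible(x)
}

#' Posterior mean divergence time in Ma
#'
#' Averages tau over pairs within each retained draw, then converts the
#' posterior of that community mean to millions of years through the
#' strict clock (`t = tau_pairwise / rate`).
#'
#' @param posterior an `habc_posterior` (or `prior_draws`).
#' @param clock_rate pairwise proportion divergence per Myr
#'   (default 0.019).
#' @return List with `estimate_Ma`, `sd_Ma` and the per-draw values
#'   (`draws_Ma`).
#' @export
mean_divergence_time <- function(posterior, clock_rate = 0.019) {
  if (clock_rate <= 0) stop("clock_rate must be > 0", call. = FALSE)
  draws <- if (inherits(posterior, "habc_posterior")) posterior$retained
           else posterior
  if (draws$n_draws == 0L) stop("empty posterior", call. = FALSE)
  mean_tau <- rowMeans(draws$tau_pair)
  t_ma <- mean_tau / clock_rate
  list(estimate_Ma = mean(t_ma),
       sd_Ma = if (length(t_ma) > 1) sd(t_ma) else 0,
       draws_Ma = t_ma)
}

#' Evaluate guild models against an hABC posterior
#'
#' Produces a model-comparison table: posterior and prior constraint
#' probabilities, Bayes factor, `2 ln BF` and Raftery category per
#' model.  Prior probabilities are computed from fresh prior draws
#' (simulation-free) at the same scenario.
#'
#' @param posterior an `habc_posterior`.
#' @param models named list of `guild_model`s (default the nine from
#'   [guild_models()] applied to the posterior's pair table).
#' @param n_prior_draws prior draws used to estimate prior probabilities
#'   (default 20000).
#' @param seed optional seed for the prior draws.
#' @return data.frame with one row per model.
#' @export
evaluate_guild_models <- function(posterior, models = NULL,
                                  n_prior_draws = 20000, seed = NULL) {
  pairs <- posterior$prior$pairs
  if (is.null(models)) models <- guild_models(pairs)
  prior <- sample_prior(posterior$scenario, pairs, n_prior_draws,
                        seed = seed, tau_max = posterior$prior$tau_max,
                        theta_max = posterior$prior$theta_max)
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    p <- constraint_probability(posterior$retained, m)
    q <- constraint_probability(prior, m)
    b <- bayes_factor(p, q)
    data.frame(model = nm, scenario = posterior$scenario,
               posterior_p = p, prior_p = q, BF = b$BF,
               two_ln_BF = b$two_ln_BF, category = b$raftery_category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
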