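as_k2p <- function(d) {
  structure(d, class = c("k2p_dist", "matrix", "array"),
            saturated = matrix(FALSE, nrow(d), ncol(d)),
            valid_sites = matrix(100L, nrow(d), ncol(d)))
}

test_that("three taxa are solved by the three-point equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(as_k2p(d))
  expect_equal(ape::Ntip(tr), 3)
  # tip branch lengths: a = (dAB + dAC - dBC)/2 etc.
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[rownames(d), colnames(d)], d, ignore_attr = TRUE)
})

test_that("NJ recovers topology and lengths from additive quartets", {
  lengths <- c(1, 2, 3, 4, 5)
  d <- quartet_distances(lengths)
  tr <- nj_tree(as_k2p(d))
  # path lengths reproduce the generating additive matrix exactly
  pl <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pl, d, tolerance = 1e-10, ignore_attr = TRUE)
  # and the topology matches the exhaustive least-squares oracle
  expect_equal(best_quartet_split(d), c("A", "B"))
  expect_true(is_monophyletic(tr, c("A", "B")))
  # random additive quartets, same check
  set.seed(11)
  for (r in 1:10) {
    dd <- quartet_distances(runif(5, 0.5, 4))
    trr <- nj_tree(as_k2p(dd))
    expect_true(is_monophyletic(trr, best_quartet_split(dd)))
  }
})

test_that("tight pairs in an ultrametric matrix become neighbours", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(0.4, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.02
  d["b1", "b2"] <- d["b2", "b1"] <- 0.04
  tr <- nj_tree(as_k2p(d))
  expect_true(is_monophyletic(tr, c("a1", "a2")))
  expect_true(is_monophyletic(tr, c("b1", "b2")))
})

test_that("NJ refuses undefined distances and tiny inputs", {
  d <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(as_k2p(d)), "a-b")
  expect_error(nj_tree(as_k2p(matrix(0, 2, 2,
                                     dimnames = list(c("x", "y"),
                                                     c("x", "y"))))),
               "three")
})

test_that("clamped trees never carry negative branch lengths", {
  set.seed(5)
  n_neg <- 0L
  for (r in 1:10) {
    base <- sample(c("A", "C", "G", "T"), 80, replace = TRUE)
    mat <- do.call(rbind, lapply(1:6, function(i) {
      x <- base
      at <- sample(80, sample(3:20, 1))
      x[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
      x
    }))
    rownames(mat) <- paste0("s", 1:6)
    dm <- distance_matrix(mat)
    raw <- ape::nj(stats::as.dist(unclass(dm)))
    if (any(raw$edge.length < 0)) n_neg <- n_neg + 1L
    tr <- nj_tree(dm)
    expect_true(all(tr$edge.length >= 0))
    # clamping preserves the topology of the raw NJ tree
    expect_equal(ape::dist.topo(ape::unroot(raw), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
  expect_gt(n_neg, 0)   # the clamp was actually exercised
})

test_that("monophyly equals bipartition membership on unrooted trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr <- ape::unroot(tr)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_false(is_monophyletic(tr, c("A", "D")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  # complement of a bipartition side is also monophyletic when unrooted
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_true(is_monophyletic(tr, "A"))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown tip")
})

test_that("MOTU sweep reproduces threshold components at every cutoff", {
  d <- matrix(c(0, 0.01, 0.05,
                0.01, 0, 0.05,
                0.05, 0.05, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  prof <- motu_sweep(as_k2p(d), cutoffs = c(0.005, 0.03, 0.05, 0.06))
  expect_equal(prof$counts, c(3L, 2L, 1L, 1L))
  p2 <- prof$partitions[, 2]
  expect_equal(p2[["A"]], p2[["B"]])
  expect_false(p2[["A"]] == p2[["C"]])

  # random fixture: counts equal a graph connected-components recount
  set.seed(9)
  mat <- random_alignment(12, 120)
  dm <- distance_matrix(mat)
  cutoffs <- seq(0, 0.8, by = 0.05)
  expect_warning(prof2 <- motu_sweep(dm, cutoffs = cutoffs), "undefined")
  for (k in seq_along(cutoffs)) {
    oracle <- brute_components(unclass(dm), cutoffs[k])
    expect_equal(prof2$counts[k], length(unique(oracle)))
    # identical partitions up to relabelling
    expect_equal(length(unique(paste(prof2$partitions[, k], oracle))),
                 length(unique(oracle)))
  }
})

test_that("MOTU partitions are nested and counts monotone", {
  set.seed(13)
  mat <- random_alignment(10, 100)
  dm <- distance_matrix(mat)
  prof <- suppressWarnings(motu_sweep(dm, cutoffs = seq(0, 0.9, by = 0.1)))
  expect_true(all(diff(prof$counts) <= 0))
  for (k in 2:length(prof$cutoffs)) {
    fine <- prof$partitions[, k - 1]
    coarse <- prof$partitions[, k]
    # each fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("the barcoding gap is the longest non-terminal plateau", {
  prof <- list(cutoffs = 1:8,
               counts = c(10L, 6L, 6L, 6L, 6L, 2L, 1L, 1L))
  g <- barcoding_gap(prof)
  expect_true(g$gap)
  expect_equal(g$motu_count, 6L)
  expect_equal(g$cutoff_low, 2)
  expect_equal(g$cutoff_high, 5)
  expect_equal(g$span, 3)
  # strictly decreasing counts: no gap, not an error
  g2 <- barcoding_gap(list(cutoffs = 1:5, counts = c(9L, 7L, 5L, 3L, 1L)))
  expect_false(g2$gap)
  # ties break toward the lower cutoff
  g3 <- barcoding_gap(list(cutoffs = 1:7,
                           counts = c(8L, 8L, 5L, 5L, 3L, 1L, 1L)))
  expect_equal(g3$motu_count, 8L)
  expect_error(barcoding_gap(list(cutoffs = 1:2, counts = c(2L, 1L))),
               ">= 3")
})

test_that("a two-species fixture shows a plateau at two MOTUs", {
  # intra <= 1%, inter >= 6% by construction
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  far <- base
  far[1:30] <- ifelse(far[1:30] == "A", "G", "A")   # ~10% apart
  mk <- function(seqv, mut, id) {
    out <- seqv
    out[mut] <- ifelse(out[mut] == "C", "T", "C")
    out
  }
  mat <- rbind(s1 = base, s2 = mk(base, 1:2), s3 = mk(base, 3:4),
               t1 = far, t2 = mk(far, 5:6), t3 = mk(far, 7:8))
  prof <- motu_sweep(distance_matrix(mat))
  g <- barcoding_gap(prof)
  expect_true(g$gap)
  expect_equal(g$motu_count, 2L)
  expect_lte(g$cutoff_low, 0.02)
  expect_gte(g$cutoff_high, 0.05)
})

# -- full delimitation --------------------------------------------------

test_that("synthetic community with clear separation is recovered exactly", {
  sim <- simulate_community(community_config(theta = 0.004, seed = 31,
                                             missing_marker_fraction = 0))
  hyp <- delimit_species(sim$dataset)
  sc <- truth_check(hyp, sim$truth)
  expect_true(sc$exact)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sum(hyp$region == "CN" & !hyp$possible_additional), 14)
  expect_equal(sum(hyp$region == "AUS" & !hyp$possible_additional), 14)
  expect_equal(nrow(attr(hyp, "conflicts")), 0)
  # flags: multi-member species all satisfy the 3% rule and monophyly
  multi <- hyp[hyp$n_members >= 2, ]
  expect_true(all(multi$within_3pct))
  expect_true(all(multi$monophyly_COI, na.rm = TRUE))
})

test_that("delimitation is invariant to sample order", {
  sim <- simulate_community(community_config(theta = 0.004, seed = 32,
                                             missing_marker_fraction = 0))
  ds <- sim$dataset
  perm <- function(a) a[sample(nrow(a)), , drop = FALSE]
  set.seed(1)
  ds2 <- build_dataset(
    list(COI = marker_alignment(perm(unclass(ds$alignments$COI)), "COI"),
         ITS2 = marker_alignment(perm(unclass(ds$alignments$ITS2)), "ITS2")),
    ds$metadata[sample(nrow(ds$metadata)), ])
  h1 <- delimit_species(ds)
  h2 <- delimit_species(ds2)
  key <- function(h) sort(vapply(strsplit(h$members, ","),
                                 function(m) paste(sort(m), collapse = ","),
                                 character(1)))
  expect_equal(key(h1), key(h2))
})

test_that("a swapped ITS2 sequence is reported as a marker conflict", {
  sim <- simulate_community(community_config(theta = 0.004, seed = 33,
                                             missing_marker_fraction = 0))
  ds <- sim$dataset
  its2 <- unclass(ds$alignments$ITS2)
  # swap the ITS2 rows of two Walkerella individuals from different species
  md <- ds$metadata
  w1 <- md$sample_id[md$species_label == "Walkerella_CN1"][1]
  w2 <- md$sample_id[md$species_label == "Walkerella_CN2"][1]
  tmp <- its2[w1, ]; its2[w1, ] <- its2[w2, ]; its2[w2, ] <- tmp
  ds2 <- build_dataset(list(COI = ds$alignments$COI,
                            ITS2 = marker_alignment(its2, "ITS2")),
                       md)
  hyp <- delimit_species(ds2)
  conf <- attr(hyp, "conflicts")
  expect_true(all(c(w1, w2) %in% conf$sample_id))
})

test_that("an ITS2-only clade is flagged as a possible additional species", {
  sim <- simulate_community(community_config(theta = 0.004, seed = 34,
                                             missing_marker_fraction = 0))
  ds <- sim$dataset
  md <- ds$metadata
  # remove COI for one whole Philotrypesis species so only its ITS2
  # clade remains (mirrors a clade with failed COI amplification)
  victims <- md$sample_id[md$species_label == "Philotrypesis_AUS2"]
  coi <- unclass(ds$alignments$COI)
  coi <- coi[!rownames(coi) %in% victims, , drop = FALSE]
  ds2 <- build_dataset(list(COI = marker_alignment(coi, "COI"),
                            ITS2 = ds$alignments$ITS2), md)
  hyp <- delimit_species(ds2)
  extra <- hyp[hyp$possible_additional, ]
  expect_equal(nrow(extra), 1)
  expect_equal(extra$genus, "Philotrypesis")
  expect_setequal(strsplit(extra$members, ",")[[1]], victims)
})

test_that("a genus sequenced once yields a low-confidence singleton", {
  coi <- marker_alignment(random_alignment(1, 60, "lone1"), "COI")
  md <- data.frame(sample_id = "lone1", genus = "Ormyrus", region = "CN",
                   guild = "large_parasitoid")
  ds <- build_dataset(list(COI = coi), md)
  hyp <- delimit_species(ds)
  expect_equal(nrow(hyp), 1)
  expect_true(hyp$low_confidence)
  expect_false(hyp$within_3pct)
})

# -- intercontinental sisters -------------------------------------------

test_that("mutual nearest cross-region species form sister pairs", {
  sim <- simulate_community(community_config(
    genera = data.frame(
      genus = c("Eupristina", "Walkerella", "Philotrypesis", "Sycoscapter",
                "Sycobia", "Sycophila"),
      guild = unname(fig_wasp_guilds[c("Eupristina", "Walkerella",
                                       "Philotrypesis", "Sycoscapter",
                                       "Sycobia", "Sycophila")]),
      n_species_CN = 1L, n_species_AUS = 1L, cross_sisters = TRUE),
    theta = 0.004, seed = 41, missing_marker_fraction = 0))
  hyp <- delimit_species(sim$dataset)
  sis <- cross_continent_sisters(sim$dataset, hyp)
  expect_equal(nrow(sis), 6)
  expect_setequal(sis$genus, sim$truth$pairs$genus)
  # the reported ranges respect intra < inter
  expect_true(all(sis$intra_max_cn < sis$inter_min, na.rm = TRUE))
})

test_that("local congeners closer than any cross-region species are not sisters", {
  # CN has two close species, AUS one distant: no mutual cross-region pair
  # for the close CN pair
  ids <- c("c1a", "c1b", "c2a", "c2b", "a1a", "a1b")
  base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  mut <- function(x, at) { x[at] <- ifelse(x[at] == "A", "C", "A"); x }
  mat <- rbind(mut(base, 1:2), mut(base, 3:4),        # CN sp1
               mut(base, 20:36), mut(base, c(20:36, 5)),   # CN sp2 (~4%)
               mut(base, 100:160), mut(base, c(100:160, 6)))  # AUS (~15%)
  rownames(mat) <- ids
  md <- data.frame(sample_id = ids, genus = "Sycophila",
                   region = c("CN", "CN", "CN", "CN", "AUS", "AUS"),
                   guild = "large_parasitoid")
  ds <- build_dataset(list(COI = marker_alignment(mat, "COI")), md)
  hyp <- delimit_species(ds)
  sis <- cross_continent_sisters(ds, hyp)
  # only one CN species can pair with the single AUS species
  expect_lte(nrow(sis), 1)
  if (nrow(sis) == 1) expect_equal(sis$n_aus, 2)
})

test_that("a single-region genus contributes no sister pairs", {
  base <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  mat <- do.call(rbind, lapply(1:4, function(i) {
    x <- base; x[i] <- ifelse(x[i] == "A", "C", "A"); x
  }))
  rownames(mat) <- paste0("ac", 1:4)
  coi <- marker_alignment(mat, "COI")
  md <- data.frame(sample_id = rownames(coi), genus = "Acophila",
                   region = "CN", guild = "large_galler")
  ds <- build_dataset(list(COI = coi), md)
  hyp <- delimit_species(ds)
  sis <- cross_continent_sisters(ds, hyp)
  expect_equal(nrow(sis), 0)
})
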