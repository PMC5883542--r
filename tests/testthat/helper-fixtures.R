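# Shared fixtures and independent oracles used across the test files.

# build a character alignment matrix from strings
aln_from_strings <- function(strings) {
  mat <- do.call(rbind, lapply(strings, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(strings)
  mat
}

write_fasta_tmp <- function(strings) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(strings)) {
    writeLines(paste0(">", nm), con)
    writeLines(strings[[nm]], con)
  }
  close(con)
  path
}

write_metadata_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_alignment <- function(n, L, ids = paste0("s", seq_len(n))) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(mat) <- ids
  mat
}

# independent site-by-site K2P recount (plain loops, no shared code path)
brute_k2p <- function(a, b) {
  n_valid <- 0L; n_ts <- 0L; n_tv <- 0L
  pur <- c("A", "G")
  for (s in seq_along(a)) {
    x <- a[s]; y <- b[s]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T")))
      next
    n_valid <- n_valid + 1L
    if (x == y) next
    if ((x %in% pur) == (y %in% pur)) n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
  }
  if (n_valid == 0L) return(list(d = NA_real_, valid = 0L, sat = TRUE))
  P <- n_ts / n_valid; Q <- n_tv / n_valid
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    return(list(d = NA_real_, valid = n_valid, sat = TRUE))
  list(d = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
       valid = n_valid, sat = FALSE)
}

# independent connected-components clustering (breadth-first search on the
# threshold graph)
brute_components <- function(d, cutoff) {
  n <- nrow(d)
  adj <- !is.na(d) & d <= cutoff
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  label <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    label <- label + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- label
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# additive distances implied by a quartet topology with given branch
# lengths: tips 1,2 on one side of the internal edge, 3,4 on the other;
# lengths = (e1, e2, e3, e4, internal)
quartet_distances <- function(lengths, ids = c("A", "B", "C", "D")) {
  e <- lengths
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d[1, 2] <- d[2, 1] <- e[1] + e[2]
  d[3, 4] <- d[4, 3] <- e[3] + e[4]
  for (i in 1:2) for (j in 3:4)
    d[i, j] <- d[j, i] <- e[i] + e[5] + e[j]
  d
}

# exhaustive least-squares fit over the three unrooted quartet topologies;
# returns the pair grouped with tip 1 in the best topology
best_quartet_split <- function(d) {
  ids <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  rss <- vapply(splits, function(sp) {
    other <- setdiff(1:4, sp)
    perm <- c(sp, other)
    dd <- d[perm, perm]
    # design: d_ij as sums of 5 edges for topology ((1,2),(3,4))
    X <- rbind(c(1, 1, 0, 0, 0),
               c(1, 0, 1, 0, 1),
               c(1, 0, 0, 1, 1),
               c(0, 1, 1, 0, 1),
               c(0, 1, 0, 1, 1),
               c(0, 0, 1, 1, 0))
    y <- c(dd[1, 2], dd[1, 3], dd[1, 4], dd[2, 3], dd[2, 4], dd[3, 4])
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  sort(ids[splits[[which.min(rss)]]])
}

# the six sister-pair table used throughout the codivergence tests
six_pair_table <- function(n = 4) {
  data.frame(
    pair_id = c("Eupristina", "Walkerella", "Philotrypesis", "Sycoscapter",
                "Sycobia", "Sycophila"),
    guild = c("pollinator", "small_galler", "small_parasitoid",
              "small_parasitoid", "large_galler", "large_parasitoid"),
    n_a = n, n_b = n, stringsAsFactors = FALSE)
}

# observed pair alignments simulated at the given per-pair tau values
observed_pairs <- function(taus, theta = 0.01, n = 4, L = 394, seed = 1) {
  lapply(seq_along(taus), function(i)
    simulate_pair(theta, theta, theta, taus[i], n, n, L,
                  seed = seed * 1000 + i))
}
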