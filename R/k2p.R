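# Kimura two-parameter distances with pairwise deletion, and the
# intra/inter-group distance summaries used by the delimitation criteria.

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns where either sequence carries a gap or `N` are dropped
#' (pairwise deletion).  With `P` and `Q` the proportions of
#' transition- and transversion-differing sites among the remaining
#' columns, the distance is
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#' When either logarithm argument is non-positive the distance is
#' saturated: `distance` is `NA` and `saturated` is `TRUE` (this is a
#' flag, not an error).
#'
#' @param a,b equal-length character vectors of residues.
#' @return List with `distance` (substitutions/site), `valid_sites`
#'   (number of pairwise-complete columns) and `saturated` (logical).
#' @export
k2p_distance <- function(a, b) {
  a <- normalize_residues(a); b <- normalize_residues(b)
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  ok <- a %in% .BASES & b %in% .BASES
  n <- sum(ok)
  if (n == 0L)
    stop("no pairwise-complete columns; distance undefined", call. = FALSE)
  av <- a[ok]; bv <- b[ok]
  diff <- av != bv
  pur_a <- av %in% c("A", "G")
  pur_b <- bv %in% c("A", "G")
  ts <- diff & (pur_a == pur_b)   # both purines or both pyrimidines
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(distance = NA_real_, valid_sites = n, saturated = TRUE))
  list(distance = -0.5 * log(arg1) - 0.25 * log(arg2) + 0,
       valid_sites = n, saturated = FALSE)
}

#' All-pairs K2P distance matrix for a marker alignment
#'
#' @param aln a [marker_alignment()] or plain character matrix with
#'   sample-id rownames.
#' @return An object of class `k2p_dist`: the symmetric numeric distance
#'   matrix (`NA` where saturated), with attributes `valid_sites`
#'   (integer matrix) and `saturated` (logical matrix).
#' @export
distance_matrix <- function(aln) {
  mat <- unclass(aln)
  if (nrow(mat) < 2L) stop("need at least two sequences", call. = FALSE)
  mat[] <- normalize_residues(mat)
  n <- nrow(mat)
  ids <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vs <- matrix(ncol(mat), n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  valid <- matrix(mat %in% .BASES, n, ncol(mat))
  purine <- matrix(mat %in% c("A", "G"), n, ncol(mat))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      nv <- sum(ok)
      vs[i, j] <- vs[j, i] <- nv
      if (nv == 0L) { d[i, j] <- d[j, i] <- NA_real_; sat[i, j] <- sat[j, i] <- TRUE; next }
      diff <- ok & (mat[i, ] != mat[j, ])
      ts <- sum(diff & (purine[i, ] == purine[j, ]))
      tv <- sum(diff) - ts
      P <- ts / nv; Q <- tv / nv
      arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
      if (arg1 <= 0 || arg2 <= 0) {
        d[i, j] <- d[j, i] <- NA_real_
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(arg1) - 0.25 * log(arg2) + 0
      }
    }
  }
  structure(d, valid_sites = vs, saturated = sat,
            class = c("k2p_dist", "matrix", "array"))
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("<k2p_dist> ", nrow(x), " x ", ncol(x),
      "; saturated entries: ", sum(attr(x, "saturated")[upper.tri(x)]),
      "\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

upper_values <- function(d) d[upper.tri(d)]

#' Intra- and inter-group distance summaries
#'
#' For every group (species, or genus-by-region) reports the number of
#' members, the range of intra-group distances (the maximum is the
#' quantity tabulated as "intrageneric K2P"), and the nearest
#' different-group partner with the min-max range of distances to it.
#' Saturated (undefined) entries are excluded and counted, never imputed.
#' A singleton group gets an `NA` intra summary, not an error.
#'
#' @param dmat a `k2p_dist` matrix (see [distance_matrix()]).
#' @param grouping named character vector (names = sample ids, values =
#'   group labels) assigning each id to exactly one group.
#' @return A data.frame with one row per group: `group`, `n`,
#'   `max_intra`, `min_intra`, `nearest_group`, `nearest_min`,
#'   `nearest_max`, `n_undefined`.
#' @export
summarize_groups <- function(dmat, grouping) {
  ids <- rownames(dmat)
  if (!all(ids %in% names(grouping)))
    stop("grouping must cover every id in the distance matrix", call. = FALSE)
  g <- grouping[ids]
  groups <- unique(g)
  out <- lapply(groups, function(gr) {
    inside <- ids[g == gr]
    outside <- ids[g != gr]
    intra <- upper_values(dmat[inside, inside, drop = FALSE])
    n_undef <- sum(is.na(intra))
    intra <- intra[!is.na(intra)]
    if (length(outside)) {
      cross <- dmat[inside, outside, drop = FALSE]
      n_undef <- n_undef + sum(is.na(cross))
      # nearest different group by minimum defined distance
      by_group <- split(seq_along(outside), g[match(outside, ids)])
      mins <- vapply(by_group, function(cols) {
        v <- cross[, cols, drop = FALSE]
        if (all(is.na(v))) Inf else min(v, na.rm = TRUE)
      }, numeric(1))
      best <- names(mins)[which.min(mins)]
      v <- cross[, by_group[[best]], drop = FALSE]
      nearest_min <- min(v, na.rm = TRUE)
      nearest_max <- max(v, na.rm = TRUE)
    } else {
      best <- NA_character_; nearest_min <- NA_real_; nearest_max <- NA_real_
    }
    data.frame(group = gr, n = length(inside),
               max_intra = if (length(intra)) max(intra) else NA_real_,
               min_intra = if (length(intra)) min(intra) else NA_real_,
               nearest_group = best,
               nearest_min = nearest_min, nearest_max = nearest_max,
               n_undefined = n_undef,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Empirical 95% threshold from pooled intraspecific distances
#'
#' The delimitation rule "within the 95% confidence interval of all
#' intraspecific distances" is implemented distributionally: the
#' threshold is the 97.5th percentile (upper bound of the central 95%
#' interval) of the pooled empirical intraspecific distance
#' distribution.
#'
#' @param intra_distances numeric vector of intraspecific distances
#'   (substitutions/site); at least two values required.
#' @return The threshold (numeric scalar).
#' @export
intraspecific_ci_threshold <- function(intra_distances) {
  x <- intra_distances[!is.na(intra_distances)]
  if (length(x) < 2L)
    stop("need at least two intraspecific distances", call. = FALSE)
  unname(quantile(x, 0.975, type = 7))
}

#' Export a distance matrix as square TSV
#' @param dmat a `k2p_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dmat, path) {
  df <- data.frame(sample_id = rownames(dmat), unclass(dmat),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a distance matrix in square PHYLIP format
#' @param dmat a `k2p_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dmat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dmat)), con)
  for (i in seq_len(nrow(dmat))) {
    nm <- sprintf("%-10s", substr(rownames(dmat)[i], 1, 10))
    writeLines(paste0(nm, paste(sprintf("%.6f", dmat[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}
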