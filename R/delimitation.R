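# Species delimitation: NJ trees, monophyly on unrooted topologies, MOTU
# cutoff sweep with barcoding-gap detection, two-marker delimitation and
# intercontinental sister-pair identification.

#' Neighbor-joining tree from a K2P distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on the distance matrix.
#' Negative branch-length estimates are clamped to zero with the deficit
#' moved to the sibling branch so tip-to-tip path lengths change as
#' little as possible.  Three taxa are solved by the closed-form
#' three-point equations.
#'
#' @param dmat a `k2p_dist` (or plain symmetric matrix with id dimnames).
#' @return An unrooted `phylo` tree over the sample ids.
#' @export
nj_tree <- function(dmat) {
  d <- unclass(dmat)
  if (nrow(d) < 3L) stop("need at least three ids for a tree", call. = FALSE)
  if (anyNA(d)) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- paste(rownames(d)[idx[, 1]], colnames(d)[idx[, 2]], sep = "-")
    stop("undefined (saturated) distances for pair(s): ",
         paste(pairs, collapse = ", "), call. = FALSE)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

# set each negative branch to 0 and add its deficit to the sibling edge
clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- which(tr$edge[, 1] == tr$edge[e, 1] & seq_along(tr$edge.length) != e)
    if (length(sib)) {
      s <- sib[1]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
    }
  }
  tr
}

#' Is a tip set monophyletic on an unrooted tree?
#'
#' On an unrooted topology a tip set is monophyletic when it is one side
#' of some edge bipartition.  The whole tip set and singletons are
#' trivially monophyletic.
#'
#' @param tree a `phylo` tree.
#' @param tip_set character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, tip_set) {
  tips <- tree$tip.label
  unknown <- setdiff(tip_set, tips)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(tip_set) == 0L) stop("empty tip set", call. = FALSE)
  tip_set <- unique(tip_set)
  if (length(tip_set) %in% c(1L, length(tips))) return(TRUE)
  # root at a tip outside the set; the set is a bipartition side iff it is
  # a clade of the rerooted tree
  out <- setdiff(tips, tip_set)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  anc <- ape::getMRCA(rooted, tip_set)
  clade <- ape::extract.clade(rooted, anc)$tip.label
  setequal(clade, tip_set)
}

#' Single-linkage MOTU clustering across a cutoff grid
#'
#' At each cutoff, sequences are clustered by single linkage: two
#' sequences share a MOTU when a chain of pairwise distances, each at or
#' below the cutoff, connects them (equivalently, connected components of
#' the threshold graph).  Undefined (saturated) distances contribute no
#' edge; their count is reported with a warning.
#'
#' @param dmat a `k2p_dist`.
#' @param cutoffs ascending numeric vector of distance cutoffs
#'   (default 0 to 10% in 0.25% steps).
#' @return An object of class `motu_profile`: list with `cutoffs`,
#'   `counts` (MOTUs per cutoff), `partitions` (id x cutoff integer
#'   matrix of cluster labels) and `n_undefined`.
#' @export
motu_sweep <- function(dmat, cutoffs = seq(0, 0.10, by = 0.0025)) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending", call. = FALSE)
  d <- unclass(dmat)
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0) {
    warning(n_undef, " undefined distance(s) treated as unlinked")
    d[is.na(d)] <- Inf
  }
  if (nrow(d) == 1L) {
    parts <- matrix(1L, 1, length(cutoffs),
                    dimnames = list(rownames(d), NULL))
  } else {
    # single-linkage dendrogram merge heights equal minimum inter-cluster
    # distances, so cutting at h reproduces the threshold components
    dd <- d
    dd[is.infinite(dd)] <- .Machine$double.xmax / 4
    hc <- stats::hclust(stats::as.dist(dd), method = "single")
    parts <- vapply(cutoffs, function(h) stats::cutree(hc, h = h),
                    integer(nrow(d)))
    if (is.null(dim(parts))) parts <- matrix(parts, nrow = 1)
    rownames(parts) <- rownames(d)
  }
  counts <- apply(parts, 2, function(p) length(unique(p)))
  structure(list(cutoffs = cutoffs, counts = as.integer(counts),
                 partitions = parts, n_undefined = n_undef),
            class = "motu_profile")
}

#' @export
print.motu_profile <- function(x, ...) {
  cat("<motu_profile> ", nrow(x$partitions), " sequences, ",
      length(x$cutoffs), " cutoffs; counts ", x$counts[1], " -> ",
      x$counts[length(x$counts)], "\n", sep = "")
  invisible(x)
}

#' Detect the barcoding gap as a MOTU-count plateau
#'
#' The barcoding gap appears as the longest run of consecutive cutoffs
#' with a constant MOTU count, excluding the terminal plateau where all
#' sequences fall in one cluster.  Ties break toward the lower cutoff.
#' A profile that never repeats a count yields a no-gap result (`gap =
#' FALSE`), not an error.
#'
#' @param profile a `motu_profile`.
#' @return List with `gap` (logical), `cutoff_low`, `cutoff_high`,
#'   `motu_count`, `span`.
#' @export
barcoding_gap <- function(profile) {
  counts <- profile$counts
  cutoffs <- profile$cutoffs
  if (length(counts) < 3L) stop("need a profile over >= 3 cutoffs", call. = FALSE)
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !(r$values == 1L & ends == length(counts))   # drop terminal one-cluster run
  cand <- which(keep & r$lengths >= 2L)
  if (!length(cand))
    return(list(gap = FALSE, cutoff_low = NA_real_, cutoff_high = NA_real_,
                motu_count = NA_integer_, span = NA_real_))
  best <- cand[which.max(r$lengths[cand])]   # which.max takes the first = lowest cutoff
  list(gap = TRUE,
       cutoff_low = cutoffs[starts[best]],
       cutoff_high = cutoffs[ends[best]],
       motu_count = as.integer(r$values[best]),
       span = cutoffs[ends[best]] - cutoffs[starts[best]])
}

#' Export a MOTU profile as TSV
#' @param profile a `motu_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motu_tsv <- function(profile, path) {
  write.table(data.frame(cutoff = profile$cutoffs, motus = profile$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# single-linkage clusters at one threshold, as an id -> label vector
threshold_clusters <- function(dmat, threshold) {
  p <- motu_sweep(dmat, cutoffs = c(threshold, threshold + 1))$partitions[, 1]
  setNames(as.integer(p), rownames(dmat))
}

#' Delimit species from a two-marker community dataset
#'
#' Applies the barcoding criteria genus by genus: the primary partition
#' is single-linkage clustering of COI K2P distances at the 3% cutoff,
#' split by region (a species never spans continents); each hypothesis
#' is then flagged for (i) monophyly on the within-genus NJ tree of each
#' marker with data for at least two members, (ii) every member having a
#' conspecific within the fixed 3% COI threshold, and (iii) the same
#' under the empirical 95% intraspecific-distance threshold.  When the
#' two rules disagree both flags are reported and the 3% rule decides
#' the partition.  Individuals whose ITS2 placement contradicts their
#' COI species are kept (COI primacy) and listed as conflicts.
#' ITS2-only individuals are attached to the nearest species within the
#' ITS2 threshold; coherent ITS2-only clusters distant from every
#' delimited species are flagged as possible additional species.
#' Genera with a single sequenced individual yield a low-confidence
#' singleton hypothesis.
#'
#' @param dataset a `community_dataset` (see [build_dataset()]).
#' @param coi_threshold fixed COI cutoff (default 0.03, i.e. 3% K2P).
#' @param its2_threshold ITS2 distance threshold used for attaching
#'   ITS2-only individuals and flagging possible extra species
#'   (default 0.03).
#' @return A data.frame of class `species_hypotheses`, one row per
#'   hypothesis, with columns `species_id`, `genus`, `region`, `guild`,
#'   `cluster_id`, `n_members`, `members` (comma-joined ids),
#'   `monophyly_COI`, `monophyly_ITS2`, `within_3pct`, `within_CI`,
#'   `low_confidence`, `possible_additional`; attributes `conflicts`
#'   (data.frame) and `ci_threshold`.
#' @export
delimit_species <- function(dataset, coi_threshold = 0.03,
                            its2_threshold = 0.03) {
  md <- dataset$metadata
  coi <- dataset$alignments$COI
  its2 <- dataset$alignments$ITS2
  if (is.null(coi) && is.null(its2))
    stop("dataset has no marker alignments", call. = FALSE)
  guild_of <- setNames(md$guild, md$genus)

  genera <- sort(unique(md$genus))
  rows <- list(); conflicts <- list()
  intra_pool <- numeric(0)
  per_genus <- list()

  for (gn in genera) {
    ids <- md$sample_id[md$genus == gn]
    coi_ids <- intersect(ids, rownames(coi))
    its2_ids <- intersect(ids, rownames(its2))
    st <- list(genus = gn, ids = ids, coi_ids = coi_ids, its2_ids = its2_ids,
               d_coi = NULL, d_its2 = NULL, cluster = NULL)
    if (length(coi_ids) >= 2L) {
      st$d_coi <- distance_matrix(coi[coi_ids, , drop = FALSE])
      st$cluster <- threshold_clusters(st$d_coi, coi_threshold)
    } else if (length(coi_ids) == 1L) {
      st$cluster <- setNames(1L, coi_ids)
    }
    if (length(its2_ids) >= 2L)
      st$d_its2 <- distance_matrix(its2[its2_ids, , drop = FALSE])
    # pool intraspecific COI distances under the primary partition
    if (!is.null(st$d_coi)) {
      cl <- st$cluster
      reg <- setNames(md$region[match(names(cl), md$sample_id)], names(cl))
      key <- paste(cl, reg[names(cl)])
      for (k in unique(key)) {
        memb <- names(cl)[key == k]
        if (length(memb) >= 2L) {
          v <- upper_values(st$d_coi[memb, memb, drop = FALSE])
          intra_pool <- c(intra_pool, v[!is.na(v)])
        }
      }
    }
    per_genus[[gn]] <- st
  }
  ci_thr <- if (length(intra_pool) >= 2L) intraspecific_ci_threshold(intra_pool)
            else NA_real_

  for (gn in genera) {
    st <- per_genus[[gn]]
    md_g <- md[md$genus == gn, , drop = FALSE]
    region_of <- setNames(md_g$region, md_g$sample_id)
    guild <- unname(guild_of[gn])

    # NJ trees per marker for monophyly flags
    tr_coi <- if (!is.null(st$d_coi) && nrow(st$d_coi) >= 3L &&
                  !anyNA(st$d_coi)) nj_tree(st$d_coi) else NULL
    tr_its2 <- if (!is.null(st$d_its2) && nrow(st$d_its2) >= 3L &&
                   !anyNA(st$d_its2)) nj_tree(st$d_its2) else NULL

    if (is.null(st$cluster) || length(st$cluster) == 0L) {
      # no COI data at all: delimit on ITS2 alone, flagged
      if (length(st$its2_ids) == 0L) next
      cl <- if (length(st$its2_ids) >= 2L)
        threshold_clusters(st$d_its2, its2_threshold)
      else setNames(1L, st$its2_ids)
      species <- split(names(cl), paste(cl, region_of[names(cl)]))
      idx <- 0L
      for (memb in species) {
        idx <- idx + 1L
        reg <- unname(region_of[memb[1]])
        rows[[length(rows) + 1L]] <- data.frame(
          species_id = paste0(gn, "_", reg, idx), genus = gn, region = reg,
          guild = guild, cluster_id = paste0(gn, "_its2only", idx),
          n_members = length(memb),
          members = paste(memb, collapse = ","),
          monophyly_COI = NA, monophyly_ITS2 = NA,
          within_3pct = NA, within_CI = NA,
          low_confidence = TRUE, possible_additional = FALSE,
          stringsAsFactors = FALSE)
      }
      next
    }

    cl <- st$cluster
    reg <- region_of[names(cl)]
    species_members <- split(names(cl), paste0(cl, ".", reg))
    # order species deterministically by cluster id then region
    species_members <- species_members[order(names(species_members))]

    # attach ITS2-only individuals to the nearest species within threshold
    its2_only <- setdiff(st$its2_ids, names(cl))
    unattached <- character(0)
    if (length(its2_only) && !is.null(st$d_its2)) {
      for (id in its2_only) {
        best <- NA_character_; bestd <- Inf
        for (k in names(species_members)) {
          sp_its2 <- intersect(species_members[[k]], st$its2_ids)
          if (!length(sp_its2)) next
          v <- st$d_its2[id, sp_its2]
          v <- v[!is.na(v)]
          if (length(v) && min(v) < bestd) { bestd <- min(v); best <- k }
        }
        if (!is.na(best) && bestd <= its2_threshold &&
            region_of[id] == region_of[species_members[[best]][1]]) {
          species_members[[best]] <- c(species_members[[best]], id)
        } else unattached <- c(unattached, id)
      }
    } else unattached <- its2_only

    # per-species rows with criterion flags
    idx_by_region <- setNames(rep(0L, length(.REGIONS)), .REGIONS)
    for (k in names(species_members)) {
      memb <- sort(species_members[[k]])
      rg <- unname(region_of[memb[1]])
      idx_by_region[rg] <- idx_by_region[rg] + 1L
      memb_coi <- intersect(memb, names(cl))
      flag3 <- flag_ci <- NA
      if (length(memb_coi) >= 2L && !is.null(st$d_coi)) {
        sub <- st$d_coi[memb_coi, memb_coi, drop = FALSE]
        nn <- apply(sub + diag(Inf, nrow(sub)), 1, min, na.rm = TRUE)
        flag3 <- all(nn <= coi_threshold)
        flag_ci <- if (is.na(ci_thr)) NA else all(nn <= ci_thr)
      } else if (length(memb_coi) == 1L) {
        flag3 <- FALSE; flag_ci <- FALSE   # no conspecific at all
      }
      mono_coi <- mono_its2 <- NA
      if (!is.null(tr_coi) && length(intersect(memb, tr_coi$tip.label)) >= 2L)
        mono_coi <- is_monophyletic(tr_coi, intersect(memb, tr_coi$tip.label))
      if (!is.null(tr_its2) && length(intersect(memb, tr_its2$tip.label)) >= 2L)
        mono_its2 <- is_monophyletic(tr_its2, intersect(memb, tr_its2$tip.label))
      cluster_global <- paste0(gn, "_c", sub("\\..*$", "", k))
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = paste0(gn, "_", rg, idx_by_region[rg]),
        genus = gn, region = rg, guild = guild,
        cluster_id = cluster_global,
        n_members = length(memb), members = paste(memb, collapse = ","),
        monophyly_COI = mono_coi, monophyly_ITS2 = mono_its2,
        within_3pct = flag3, within_CI = flag_ci,
        low_confidence = length(memb) == 1L,
        possible_additional = FALSE, stringsAsFactors = FALSE)
    }

    # coherent clusters of unattached ITS2-only individuals: possible
    # additional species (mirrors a clade with failed COI amplification)
    if (length(unattached) >= 2L) {
      du <- distance_matrix(
        its2[unattached, , drop = FALSE])
      clu <- threshold_clusters(du, its2_threshold)
      extra_i <- 0L
      for (u in unique(clu)) {
        memb <- sort(names(clu)[clu == u])
        if (length(memb) < 2L) next
        extra_i <- extra_i + 1L
        rg <- unname(region_of[memb[1]])
        rows[[length(rows) + 1L]] <- data.frame(
          species_id = paste0(gn, "_", rg, "_extra", extra_i),
          genus = gn, region = rg, guild = guild,
          cluster_id = paste0(gn, "_extra", extra_i),
          n_members = length(memb), members = paste(memb, collapse = ","),
          monophyly_COI = NA,
          monophyly_ITS2 = if (!is.null(tr_its2) &&
                               all(memb %in% tr_its2$tip.label))
            is_monophyletic(tr_its2, memb) else NA,
          within_3pct = NA, within_CI = NA,
          low_confidence = TRUE, possible_additional = TRUE,
          stringsAsFactors = FALSE)
      }
    }

    # marker incongruence: an individual whose nearest ITS2 neighbour
    # belongs to a different COI species while own-species ITS2 members
    # exist and are farther
    if (!is.null(st$d_its2)) {
      sp_of <- setNames(rep(names(species_members),
                            lengths(species_members)),
                        unlist(species_members))
      both <- intersect(names(cl), st$its2_ids)
      for (id in both) {
        own <- setdiff(intersect(species_members[[sp_of[id]]], st$its2_ids), id)
        if (!length(own)) next
        others <- setdiff(st$its2_ids, c(id, own))
        if (!length(others)) next
        d_own <- suppressWarnings(min(st$d_its2[id, own], na.rm = TRUE))
        d_oth <- suppressWarnings(min(st$d_its2[id, others], na.rm = TRUE))
        if (is.finite(d_oth) && d_oth < d_own) {
          nn <- others[which.min(st$d_its2[id, others])]
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            sample_id = id, genus = gn,
            coi_species = sp_of[id], its2_nearest = unname(sp_of[nn]),
            reason = "ITS2 nearest neighbour in a different COI species",
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(0))
  rownames(out) <- NULL
  structure(out,
            conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                        else data.frame(sample_id = character(0)),
            ci_threshold = ci_thr,
            coi_threshold = coi_threshold,
            class = c("species_hypotheses", "data.frame"))
}

#' Intercontinental sister-species pairs
#'
#' Within each genus, computes for every delimited species its nearest
#' heterospecific (by minimum COI K2P distance between members).  Two
#' species form an intercontinental sister pair when each is the other's
#' nearest heterospecific and they come from different regions.
#' Reported with the min-max K2P within each member and between the two.
#' A genus present in only one region contributes nothing.
#'
#' @param dataset a `community_dataset`.
#' @param hypotheses a `species_hypotheses` data.frame from
#'   [delimit_species()].
#' @return data.frame with one row per sister pair: `genus`,
#'   `species_cn`, `species_aus`, `inter_min`, `inter_max`,
#'   `intra_max_cn`, `intra_max_aus`, `n_cn`, `n_aus`.
#' @export
cross_continent_sisters <- function(dataset, hypotheses) {
  coi <- dataset$alignments$COI
  out <- list()
  hyp <- hypotheses[!hypotheses$possible_additional, , drop = FALSE]
  for (gn in unique(hyp$genus)) {
    h <- hyp[hyp$genus == gn, , drop = FALSE]
    if (length(unique(h$region)) < 2L) next
    members <- lapply(strsplit(h$members, ","), intersect, rownames(coi))
    names(members) <- h$species_id
    members <- members[lengths(members) > 0]
    if (length(members) < 2L) next
    all_ids <- unlist(members)
    dm <- distance_matrix(coi[all_ids, , drop = FALSE])
    sp <- names(members)
    # min and max defined distance between each pair of species
    mind <- maxd <- matrix(NA_real_, length(sp), length(sp),
                           dimnames = list(sp, sp))
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      if (i == j) next
      v <- dm[members[[i]], members[[j]], drop = FALSE]
      v <- v[!is.na(v)]
      if (length(v)) { mind[i, j] <- min(v); maxd[i, j] <- max(v) }
    }
    nearest <- apply(mind, 1, function(r)
      if (all(is.na(r))) NA_character_ else sp[which.min(r)])
    reg <- setNames(h$region[match(sp, h$species_id)], sp)
    seen <- character(0)
    for (s in sp) {
      partner <- nearest[[s]]
      if (is.na(partner) || partner %in% seen) next
      if (identical(nearest[[partner]], s) && reg[s] != reg[partner]) {
        seen <- c(seen, s, partner)
        cn <- if (reg[s] == "CN") s else partner
        au <- if (reg[s] == "CN") partner else s
        intra_max <- function(x) {
          v <- upper_values(dm[members[[x]], members[[x]], drop = FALSE])
          v <- v[!is.na(v)]
          if (length(v)) max(v) else NA_real_
        }
        out[[length(out) + 1L]] <- data.frame(
          genus = gn, species_cn = cn, species_aus = au,
          inter_min = mind[cn, au], inter_max = maxd[cn, au],
          intra_max_cn = intra_max(cn), intra_max_aus = intra_max(au),
          n_cn = length(members[[cn]]), n_aus = length(members[[au]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(genus = character(0), species_cn = character(0),
                      species_aus = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export species hypotheses as TSV and JSON
#' @param hypotheses a `species_hypotheses` data.frame.
#' @param tsv,json optional output paths.
#' @return Invisibly, the list of written paths.
#' @export
write_species_hypotheses <- function(hypotheses, tsv = NULL, json = NULL) {
  written <- character(0)
  if (!is.null(tsv)) {
    write.table(as.data.frame(hypotheses), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(json)) {
    obj <- list(species = as.data.frame(hypotheses),
                conflicts = attr(hypotheses, "conflicts"),
                ci_threshold = attr(hypotheses, "ci_threshold"),
                coi_threshold = attr(hypotheses, "coi_threshold"))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), json)
    written <- c(written, json)
  }
  invisible(written)
}
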