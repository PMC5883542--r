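# Synthetic two-region fig wasp communities with known truth: the
# test-bed standing in for field/GenBank data, built on the same
# isolation-coalescent machinery as the hABC.

#' Configuration for a synthetic community
#'
#' The default configuration reproduces the composition skeleton of the
#' *F. benjamina* study system: nine genera over five guilds, fourteen
#' species per region, six shared genera each contributing one
#' intercontinental sister pair, China-only *Acophila* and *Ormyrus*,
#' Australia-only *Sycorycteridea*, COI standardized to 394 bp and a
#' slower indel-free ITS2.
#'
#' @param genera data.frame with columns `genus`, `guild`,
#'   `n_species_CN`, `n_species_AUS`, `cross_sisters` (logical: does the
#'   genus contribute a sister pair).  Default: the nine-genus skeleton.
#' @param n_individuals sequences per species per marker (default 4).
#' @param L_COI,L_ITS2 alignment lengths (defaults 394 and 400).
#' @param theta population mutation parameter per species
#'   (default 0.01).
#' @param tau_Ma divergence times of the sister pairs in Ma: a single
#'   shared value (default 5.2), a vector named by guild, or a vector
#'   named by genus.
#' @param clock_rate COI clock, pairwise proportion per Myr
#'   (default 0.019).
#' @param its2_rate_factor ITS2 rate relative to COI (default 0.3).
#' @param congener_div pairwise COI divergence between non-sister
#'   congeners (default 0.24, i.e. about 12.6 Ma of separation).
#' @param missing_marker_fraction fraction of samples that lose one
#'   randomly chosen marker (default 0.1).
#' @param seed integer seed.
#' @return List of class `community_config`.
#' @export
community_config <- function(genera = NULL, n_individuals = 4,
                             L_COI = 394, L_ITS2 = 400, theta = 0.01,
                             tau_Ma = 5.2, clock_rate = 0.019,
                             its2_rate_factor = 0.3, congener_div = 0.24,
                             missing_marker_fraction = 0.1, seed = 1L) {
  if (is.null(genera)) {
    genera <- data.frame(
      genus = c("Eupristina", "Philotrypesis", "Sycoscapter",
                "Sycorycteridea", "Walkerella", "Sycobia", "Sycophila",
                "Acophila", "Ormyrus"),
      guild = unname(fig_wasp_guilds[c("Eupristina", "Philotrypesis",
                                       "Sycoscapter", "Sycorycteridea",
                                       "Walkerella", "Sycobia", "Sycophila",
                                       "Acophila", "Ormyrus")]),
      n_species_CN = c(1L, 4L, 2L, 0L, 2L, 1L, 2L, 1L, 1L),
      n_species_AUS = c(1L, 3L, 3L, 1L, 2L, 1L, 3L, 0L, 0L),
      cross_sisters = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                        FALSE, FALSE),
      stringsAsFactors = FALSE)
  }
  bad <- genera$cross_sisters &
    (genera$n_species_CN < 1L | genera$n_species_AUS < 1L)
  if (any(bad))
    stop("cross_sisters requested for genus absent in one region: ",
         paste(genera$genus[bad], collapse = ", "), call. = FALSE)
  stopifnot(all(tau_Ma >= 0), theta > 0,
            missing_marker_fraction >= 0, missing_marker_fraction <= 1,
            n_individuals >= 1)
  structure(list(genera = genera, n_individuals = n_individuals,
                 L_COI = L_COI, L_ITS2 = L_ITS2, theta = theta,
                 tau_Ma = tau_Ma, clock_rate = clock_rate,
                 its2_rate_factor = its2_rate_factor,
                 congener_div = congener_div,
                 missing_marker_fraction = missing_marker_fraction,
                 seed = as.integer(seed)),
            class = "community_config")
}

#' Read a community configuration from YAML
#' @param path YAML file whose keys match the arguments of
#'   [community_config()] (`genera` as a list of records).
#' @return A `community_config`.
#' @export
read_community_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genera))
    y$genera <- do.call(rbind, lapply(y$genera, as.data.frame))
  if (!is.null(y$tau_Ma)) y$tau_Ma <- unlist(y$tau_Ma)
  do.call(community_config, y)
}

tau_for_pair <- function(tau_Ma, genus, guild) {
  if (length(tau_Ma) == 1L && is.null(names(tau_Ma))) return(unname(tau_Ma))
  if (!is.null(names(tau_Ma)) && genus %in% names(tau_Ma))
    return(unname(tau_Ma[genus]))
  if (!is.null(names(tau_Ma)) && guild %in% names(tau_Ma))
    return(unname(tau_Ma[guild]))
  stop("tau_Ma gives no value for genus ", genus, " / guild ", guild,
       call. = FALSE)
}

random_root <- function(L) sample.int(4L, L, replace = TRUE) - 1L

#' Simulate a complete synthetic two-region community
#'
#' Every genus gets an independent ancestral sequence per marker.
#' Non-sister species hang from it as single coalescent populations at
#' half the configured congener divergence; each cross-continental
#' sister pair is generated by the two-population isolation coalescent
#' at `tau = tau_Ma * clock_rate` (COI) with the pair's subtree grafted
#' at the same depth.  ITS2 uses the same machinery with all times
#' scaled by `its2_rate_factor` and no indels.  A configured fraction of
#' samples loses one randomly chosen marker.  Fully reproducible under
#' the config seed.
#'
#' @param config a [community_config()].
#' @param outdir optional directory; when given, writes `coi.fasta`,
#'   `its2.fasta`, `metadata.tsv` and `truth.json` there.
#' @return List of class `synthetic_community`: `dataset` (a
#'   `community_dataset`), `truth` (list with `samples`, `pairs`,
#'   `species`, `seed`), and `files` (paths or `NULL`).
#' @export
simulate_community <- function(config, outdir = NULL) {
  set.seed(config$seed)
  rate <- config$clock_rate
  markers <- list(
    COI = list(L = config$L_COI, scale = 1),
    ITS2 = list(L = config$L_ITS2, scale = config$its2_rate_factor))
  seqs <- list(COI = list(), ITS2 = list())
  samples <- list(); pair_truth <- list()

  for (gi in seq_len(nrow(config$genera))) {
    g <- config$genera[gi, ]
    roots <- lapply(markers, function(m) random_root(m$L))
    species <- list()  # list of (label, region, n)
    if (g$cross_sisters) {
      tau_ma <- tau_for_pair(config$tau_Ma, g$genus, g$guild)
      pair_truth[[length(pair_truth) + 1L]] <- data.frame(
        genus = g$genus, guild = g$guild, tau_Ma = tau_ma,
        tau_subst = tau_ma * rate, theta = config$theta,
        species_cn = paste0(g$genus, "_CN1"),
        species_aus = paste0(g$genus, "_AUS1"),
        stringsAsFactors = FALSE)
    }
    for (rg in .REGIONS) {
      n_sp <- if (rg == "CN") g$n_species_CN else g$n_species_AUS
      if (n_sp > 0)
        species <- c(species, lapply(seq_len(n_sp), function(k)
          list(label = paste0(g$genus, "_", rg, k), region = rg, k = k)))
    }
    for (m in names(markers)) {
      L <- markers[[m]]$L; sc <- markers[[m]]$scale
      radius <- config$congener_div * sc / 2
      done_pair <- FALSE
      for (sp in species) {
        is_pair_member <- g$cross_sisters && sp$k == 1L
        if (is_pair_member && sp$region == "AUS") next  # emitted with CN side
        n <- config$n_individuals
        if (is_pair_member) {
          tau_ma <- tau_for_pair(config$tau_Ma, g$genus, g$guild)
          mat <- .sim_isolation_pair_cpp(
            config$theta * sc, config$theta * sc, config$theta * sc,
            tau_ma * rate * sc, n, n, L, radius, roots[[m]])
          ids <- c(paste0(g$genus, "_CN1_", seq_len(n)),
                   paste0(g$genus, "_AUS1_", seq_len(n)))
          done_pair <- TRUE
        } else {
          mat <- .sim_isolation_pair_cpp(
            config$theta * sc, config$theta * sc, config$theta * sc,
            0, n, 0L, L, radius, roots[[m]])
          ids <- paste0(sp$label, "_", seq_len(n))
        }
        rownames(mat) <- ids
        seqs[[m]][[length(seqs[[m]]) + 1L]] <- int_to_base(mat)
      }
      stopifnot(!g$cross_sisters || done_pair)
    }
    for (sp in species) {
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = paste0(sp$label, "_", seq_len(config$n_individuals)),
        genus = g$genus, region = sp$region, guild = g$guild,
        species_label = sp$label, stringsAsFactors = FALSE)
    }
  }

  meta <- do.call(rbind, samples)
  aln <- lapply(seqs, function(s) do.call(rbind, s))
  # drop one marker for a random subset of samples
  n_missing <- floor(config$missing_marker_fraction * nrow(meta))
  if (n_missing > 0) {
    drop_ids <- sort(sample(meta$sample_id, n_missing))
    drop_marker <- setNames(sample(.MARKERS, n_missing, replace = TRUE),
                            drop_ids)
    for (m in .MARKERS) {
      gone <- names(drop_marker)[drop_marker == m]
      aln[[m]] <- aln[[m]][!rownames(aln[[m]]) %in% gone, , drop = FALSE]
    }
  } else drop_marker <- character(0)

  alignments <- list(COI = marker_alignment(aln$COI, "COI"),
                     ITS2 = marker_alignment(aln$ITS2, "ITS2"))
  dataset <- build_dataset(alignments, meta)
  truth <- list(
    samples = meta,
    pairs = if (length(pair_truth)) do.call(rbind, pair_truth) else
      data.frame(genus = character(0)),
    species = split(meta$sample_id, meta$species_label),
    dropped_marker = as.list(drop_marker),
    seed = config$seed)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      coi = file.path(outdir, "coi.fasta"),
      its2 = file.path(outdir, "its2.fasta"),
      metadata = file.path(outdir, "metadata.tsv"),
      truth = file.path(outdir, "truth.json"))
    write_fasta_alignment(alignments$COI, files$coi)
    write_fasta_alignment(alignments$ITS2, files$its2)
    write.table(meta, files$metadata, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), files$truth)
  }
  structure(list(dataset = dataset, truth = truth, files = files),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community> ", length(x$truth$species), " species, ",
      nrow(x$truth$samples), " samples, ", nrow(x$truth$pairs),
      " sister pairs (seed ", x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Score pipeline output against the generating truth
#'
#' Species recovery is scored by set matching: precision is the mean,
#' over delimited species, of the best overlap fraction with any true
#' species; recall is the mean, over true species, of the best overlap
#' fraction with any delimited species (so a true species split in two
#' is penalised on recall).  `exact` is `TRUE` when the two partitions
#' coincide.  Optionally scores divergence-time recovery (posterior
#' mean against the true shared time) and clock dating (per-pair
#' absolute error).
#'
#' @param hypotheses a `species_hypotheses` data.frame (possible
#'   additional species are ignored for matching).
#' @param truth the `truth` element of a [simulate_community()] result.
#' @param posterior optional `habc_posterior`; scored when the truth has
#'   a single shared divergence time.
#' @param dating optional data.frame from [date_sister_pairs()].
#' @param clock_rate clock used for the posterior conversion.
#' @return List of class `truth_scorecard`: `precision`, `recall`,
#'   `exact`, `n_true`, `n_delimited`, and optional `tau_error_Ma`,
#'   `dating_error_Ma`.
#' @export
truth_check <- function(hypotheses, truth, posterior = NULL,
                        dating = NULL, clock_rate = 0.019) {
  hyp <- as.data.frame(hypotheses)
  hyp <- hyp[!hyp$possible_additional, , drop = FALSE]
  delim <- lapply(strsplit(hyp$members, ","), sort)
  names(delim) <- hyp$species_id
  true_sp <- lapply(truth$species, sort)
  known <- unlist(true_sp)
  if (length(delim)) {
    bad <- setdiff(unlist(delim), known)
    if (length(bad))
      stop("delimited member id(s) absent from truth: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  overlap_frac <- function(x, pool, denom) {
    if (!length(pool)) return(0)
    max(vapply(pool, function(y) length(intersect(x, y)), numeric(1))) /
      denom
  }
  precision <- if (!length(delim)) NA_real_ else
    mean(vapply(delim, function(d) overlap_frac(d, true_sp, length(d)),
                numeric(1)))
  recall <- if (!length(delim)) 0 else
    mean(vapply(true_sp, function(t) overlap_frac(t, delim, length(t)),
                numeric(1)))
  exact <- length(delim) == length(true_sp) &&
    all(sort(vapply(delim, paste, character(1), collapse = ",")) ==
          sort(vapply(true_sp, paste, character(1), collapse = ",")))
  out <- list(precision = precision, recall = recall, exact = exact,
              n_true = length(true_sp), n_delimited = length(delim))
  if (!is.null(posterior) && nrow(truth$pairs)) {
    est <- mean_divergence_time(posterior, clock_rate)
    out$tau_error_Ma <- abs(est$estimate_Ma - mean(truth$pairs$tau_Ma))
  }
  if (!is.null(dating) && nrow(truth$pairs)) {
    tt <- truth$pairs$tau_Ma[match(dating$genus, truth$pairs$genus)]
    out$dating_error_Ma <- abs(dating$t_Ma - tt)
  }
  class(out) <- "truth_scorecard"
  out
}

#' @export
print.truth_scorecard <- function(x, ...) {
  cat("<truth_scorecard> precision ", format(x$precision, digits = 4),
      ", recall ", format(x$recall, digits = 4),
      if (isTRUE(x$exact)) " (exact)" else "", "\n", sep = "")
  invisible(x)
}
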