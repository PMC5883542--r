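# Genus x region x guild community composition tables and the
# intercontinental comparison.

#' Build a community composition table
#'
#' Counts delimited species per genus and region, carries the guild from
#' the genus-to-guild map, tabulates possible extra species separately,
#' and (when a distance matrix is supplied) reports the maximum
#' intrageneric K2P per genus and region in percent.
#'
#' @param hypotheses a `species_hypotheses` data.frame from
#'   [delimit_species()], or a counts data.frame with columns `genus`,
#'   `guild`, `n_CN`, `n_AUS` (and optionally `extra_CN`, `extra_AUS`,
#'   `max_intra_CN`, `max_intra_AUS`) as produced by hand-entering a
#'   published table.
#' @param dataset optional `community_dataset` used to compute
#'   intrageneric COI K2P ranges.
#' @return An object of class `community_table`: data.frame with one row
#'   per genus (`genus`, `guild`, `n_CN`, `n_AUS`, `extra_CN`,
#'   `extra_AUS`, `max_intra_CN`, `max_intra_AUS`) plus a `totals`
#'   attribute (species per region, with extras as a range).
#' @export
community_table <- function(hypotheses, dataset = NULL) {
  if (!inherits(hypotheses, "species_hypotheses") &&
      all(c("genus", "guild", "n_CN", "n_AUS") %in% names(hypotheses))) {
    df <- as.data.frame(hypotheses)
    for (cc in c("extra_CN", "extra_AUS"))
      if (is.null(df[[cc]])) df[[cc]] <- 0L
    for (cc in c("max_intra_CN", "max_intra_AUS"))
      if (is.null(df[[cc]])) df[[cc]] <- NA_real_
    return(finish_community_table(df))
  }
  hyp <- as.data.frame(hypotheses)
  if (!nrow(hyp)) {
    df <- data.frame(genus = character(0), guild = character(0),
                     n_CN = integer(0), n_AUS = integer(0),
                     extra_CN = integer(0), extra_AUS = integer(0),
                     max_intra_CN = numeric(0), max_intra_AUS = numeric(0))
    return(finish_community_table(df))
  }
  missing_guild <- unique(hyp$genus[is.na(hyp$guild) | !nzchar(hyp$guild)])
  if (length(missing_guild))
    stop("genus lacking a guild mapping: ",
         paste(missing_guild, collapse = ", "), call. = FALSE)
  genera <- sort(unique(hyp$genus))
  cnt <- function(gn, rg, extra) {
    sum(hyp$genus == gn & hyp$region == rg &
          hyp$possible_additional == extra)
  }
  df <- data.frame(
    genus = genera,
    guild = hyp$guild[match(genera, hyp$genus)],
    n_CN = vapply(genera, cnt, integer(1) + 0L, rg = "CN", extra = FALSE),
    n_AUS = vapply(genera, cnt, integer(1) + 0L, rg = "AUS", extra = FALSE),
    extra_CN = vapply(genera, cnt, integer(1) + 0L, rg = "CN", extra = TRUE),
    extra_AUS = vapply(genera, cnt, integer(1) + 0L, rg = "AUS", extra = TRUE),
    max_intra_CN = NA_real_, max_intra_AUS = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(dataset) && !is.null(dataset$alignments$COI)) {
    md <- dataset$metadata
    coi <- dataset$alignments$COI
    for (i in seq_len(nrow(df))) {
      for (rg in .REGIONS) {
        ids <- intersect(md$sample_id[md$genus == df$genus[i] &
                                        md$region == rg], rownames(coi))
        if (length(ids) >= 2L) {
          v <- upper_values(distance_matrix(coi[ids, , drop = FALSE]))
          v <- v[!is.na(v)]
          if (length(v))
            df[i, paste0("max_intra_", rg)] <- 100 * max(v)
        }
      }
    }
  }
  finish_community_table(df)
}

finish_community_table <- function(df) {
  rownames(df) <- NULL
  totals <- list(
    n_species = c(CN = sum(df$n_CN), AUS = sum(df$n_AUS)),
    n_with_extras = c(CN = sum(df$n_CN) + sum(df$extra_CN),
                      AUS = sum(df$n_AUS) + sum(df$extra_AUS)))
  structure(df, totals = totals,
            class = c("community_table", "data.frame"))
}

#' @export
print.community_table <- function(x, ...) {
  print(as.data.frame(x))
  t <- attr(x, "totals")
  rng <- function(rg) {
    lo <- t$n_species[rg]; hi <- t$n_with_extras[rg]
    if (hi > lo) paste0(lo, "-", hi) else as.character(lo)
  }
  cat("Totals: CN ", rng("CN"), ", AUS ", rng("AUS"),
      " species (extras as range)\n", sep = "")
  invisible(x)
}

#' Compare community composition between the two regions
#'
#' From a [community_table()] covering both regions: shared genera
#' (present in both), region-exclusive genera, per-region species
#' richness (extras reported as a range), per-guild species counts per
#' region, and the number of shared species.  When the table derives
#' from delimited hypotheses, shared species are counted through the
#' genus-level COI cluster ids recorded before the region split (a 3%
#' cluster spanning both continents); a hand-entered counts table has no
#' cluster structure and `shared_species` is taken as 0 unless supplied.
#'
#' @param tab a `community_table`.
#' @param hypotheses optional `species_hypotheses` used to count shared
#'   species through cluster ids.
#' @return List of class `composition_comparison`.
#' @export
compare_communities <- function(tab, hypotheses = NULL) {
  df <- as.data.frame(tab)
  present_cn <- df$genus[df$n_CN + df$extra_CN > 0]
  present_aus <- df$genus[df$n_AUS + df$extra_AUS > 0]
  if (!length(present_cn) || !length(present_aus))
    stop("table must cover both regions", call. = FALSE)
  shared <- intersect(present_cn, present_aus)
  shared_species <- 0L
  if (!is.null(hypotheses)) {
    hyp <- as.data.frame(hypotheses)
    hyp <- hyp[!hyp$possible_additional, , drop = FALSE]
    byc <- split(hyp$region, hyp$cluster_id)
    shared_species <- sum(vapply(byc, function(r)
      all(.REGIONS %in% r), logical(1)))
  }
  guild_counts <- vapply(.REGIONS, function(rg) {
    vapply(GUILDS, function(g)
      sum(df[df$guild == g, paste0("n_", rg)]), integer(1) + 0L)
  }, setNames(numeric(length(GUILDS)), GUILDS))
  t <- attr(tab, "totals")
  structure(list(
    shared_genera = list(count = length(shared), genera = sort(shared)),
    region_exclusive_genera = list(
      CN = sort(setdiff(present_cn, present_aus)),
      AUS = sort(setdiff(present_aus, present_cn))),
    shared_species = shared_species,
    richness = t$n_species,
    richness_with_extras = t$n_with_extras,
    guild_counts = guild_counts),
    class = "composition_comparison")
}

#' @export
print.composition_comparison <- function(x, ...) {
  cat("Shared genera (", x$shared_genera$count, "): ",
      paste(x$shared_genera$genera, collapse = ", "), "\n",
      "CN-only: ", paste(x$region_exclusive_genera$CN, collapse = ", "),
      "; AUS-only: ",
      paste(x$region_exclusive_genera$AUS, collapse = ", "), "\n",
      "Richness: CN ", x$richness["CN"], ", AUS ", x$richness["AUS"],
      "; shared species: ", x$shared_species, "\n", sep = "")
  print(x$guild_counts)
  invisible(x)
}

#' Published community composition of F. benjamina fig wasps
#'
#' Loads the hand-entered genus-by-region species counts (with maximum
#' intrageneric COI K2P percentages and possible extra species) for the
#' Chinese and Australian *F. benjamina* communities, shipped as a
#' plain-text fixture.
#'
#' @return A `community_table`.
#' @export
benjamina_community_table <- function() {
  path <- system.file("extdata", "benjamina_table1.tsv",
                      package = "figcodiv", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  community_table(df)
}

#' Write a community table as TSV and a Markdown report
#' @param tab a `community_table`.
#' @param tsv,md optional output paths.
#' @return Invisibly, the written paths.
#' @export
write_community_table <- function(tab, tsv = NULL, md = NULL) {
  written <- character(0)
  df <- as.data.frame(tab)
  if (!is.null(tsv)) {
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(md)) {
    t <- attr(tab, "totals")
    lines <- c("| Genus | Guild | CN species | CN max K2P% | AUS species | AUS max K2P% |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s | %s |",
                       df$genus, df$guild,
                       ifelse(df$extra_CN > 0,
                              paste0(df$n_CN, " (+", df$extra_CN, "?)"),
                              df$n_CN),
                       ifelse(is.na(df$max_intra_CN), "-",
                              sprintf("%.1f", df$max_intra_CN)),
                       ifelse(df$extra_AUS > 0,
                              paste0(df$n_AUS, " (+", df$extra_AUS, "?)"),
                              df$n_AUS),
                       ifelse(is.na(df$max_intra_AUS), "-",
                              sprintf("%.1f", df$max_intra_AUS))),
               sprintf("| **Total** |  | **%d** |  | **%d** |  |",
                       t$n_species["CN"], t$n_species["AUS"]))
    writeLines(lines, md)
    written <- c(written, md)
  }
  invisible(written)
}
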