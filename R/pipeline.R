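# Stage orchestration: simulate -> delimit -> codiverge -> date ->
# compare, with config, seeds, logging and a JSON run manifest.

pkg_version <- function() as.character(utils::packageVersion("figcodiv"))

log_msg <- function(..., log_json = NULL, level = "info") {
  msg <- paste0(...)
  message("[figcodiv] ", msg)
  if (!is.null(log_json))
    cat(jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                              level = level, msg = msg), auto_unbox = TRUE),
        "\n", file = log_json, append = TRUE)
  invisible(msg)
}

hash_files <- function(paths) {
  paths <- unlist(paths)
  paths <- paths[!is.na(paths) & file.exists(paths)]
  as.list(tools::md5sum(paths))
}

manifest_path <- function(outdir) file.path(outdir, "manifest.json")

read_manifest <- function(outdir) {
  p <- manifest_path(outdir)
  if (!file.exists(p)) return(list())
  jsonlite::read_json(p)
}

write_manifest <- function(outdir, manifest) {
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             manifest_path(outdir))
  invisible(manifest)
}

stage_current <- function(manifest, stage, in_hash) {
  st <- manifest[[stage]]
  if (is.null(st)) return(FALSE)
  norm <- function(x) {
    x <- lapply(x, as.character)
    x[order(names(x))]
  }
  identical(norm(st$input_hashes), norm(in_hash)) &&
    all(file.exists(unlist(st$outputs)))
}

record_stage <- function(manifest, stage, in_hash, outputs, config, seed) {
  manifest[[stage]] <- list(
    stage = stage, seed = seed, config = config,
    input_hashes = in_hash, outputs = outputs,
    version = pkg_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest
}

#' Default pipeline configuration
#'
#' Nested list of per-stage settings that [run_pipeline()] starts from;
#' a user config overrides entries by name.  `simulate` holds
#' [community_config()] arguments; `delimit` the two distance
#' thresholds; `codiverge` the prior scenarios and ABC settings; `date`
#' the clock and bootstrap settings.
#'
#' @return Nested list of stage settings.
#' @export
default_pipeline_config <- function() {
  list(simulate = list(),               # community_config() arguments
       delimit = list(coi_threshold = 0.03, its2_threshold = 0.03),
       codiverge = list(scenarios = c(2, 4, 6), n_sims = 5000,
                        keep_fraction = 0.01, tau_max = 0.35,
                        theta_max = 0.02),
       date = list(rate = 0.019, correction = "net_between",
                   n_boot = 1000))
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(extra[[nm]]))
      merge_config(base[[nm]], extra[[nm]]) else extra[[nm]]
  }
  base
}

load_dataset_files <- function(datadir) {
  paths <- file.path(datadir, c("coi.fasta", "its2.fasta", "metadata.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing upstream input(s): ", paste(missing, collapse = ", "),
         "\nrun the simulate stage (or place data files) first",
         call. = FALSE)
  build_dataset(list(COI = read_fasta_alignment(paths[1], "COI"),
                     ITS2 = read_fasta_alignment(paths[2], "ITS2")),
                read_metadata(paths[3]))
}

#' Run the analysis pipeline
#'
#' Executes the stages in dependency order.  `simulate` writes a
#' synthetic community with truth; `delimit` reads the data files and
#' writes species hypotheses, the MOTU profile and per-genus NJ trees;
#' `codiverge` builds the sister-pair table and runs the hABC over the
#' configured scenarios, writing a model-comparison table; `date`
#' writes strict-clock split estimates; `compare` writes the community
#' table and intercontinental comparison; `all` chains every stage.
#' Each stage records its config, seed, input hashes and outputs in
#' `manifest.json`; a rerun with unchanged inputs and config skips the
#' stage.
#'
#' @param subcommand one of `"simulate"`, `"delimit"`, `"codiverge"`,
#'   `"date"`, `"compare"`, `"all"`.
#' @param outdir output directory (data files live in `outdir/data`).
#' @param config nested list overriding [default_pipeline_config()]
#'   entries, or a path to a YAML file with the same structure.
#' @param seed master seed applied to every stochastic stage.
#' @param log_level unused placeholder for CLI symmetry.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "delimit",
                                        "codiverge", "date", "compare"),
                         outdir, config = list(), seed = 1L,
                         log_level = "info") {
  subcommand <- match.arg(subcommand)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_json <- file.path(outdir, "log.jsonl")
  manifest <- read_manifest(outdir)
  stages <- if (subcommand == "all")
    c("simulate", "delimit", "codiverge", "date", "compare")
  else subcommand
  datadir <- file.path(outdir, "data")

  for (stage in stages) {
    res <- switch(stage,
      simulate = {
        sc_args <- cfg$simulate; sc_args$seed <- seed
        in_hash <- list(config = as.character(
          jsonlite::toJSON(sc_args, auto_unbox = TRUE, digits = NA)))
        if (stage_current(manifest, stage, in_hash)) {
          log_msg("simulate: up to date, skipped", log_json = log_json)
          next
        }
        sim <- simulate_community(do.call(community_config, sc_args),
                                  outdir = datadir)
        manifest <- record_stage(manifest, stage, in_hash,
                                 sim$files, sc_args, seed)
        log_msg("simulate: wrote ", length(sim$files), " files",
                log_json = log_json)
      },
      delimit = {
        in_files <- file.path(datadir, c("coi.fasta", "its2.fasta",
                                         "metadata.tsv"))
        in_hash <- c(hash_files(in_files),
                     list(config = as.character(
                       jsonlite::toJSON(cfg$delimit, auto_unbox = TRUE))))
        if (stage_current(manifest, stage, in_hash)) {
          log_msg("delimit: up to date, skipped", log_json = log_json)
          next
        }
        ds <- load_dataset_files(datadir)
        hyp <- delimit_species(ds, cfg$delimit$coi_threshold,
                               cfg$delimit$its2_threshold)
        dm <- distance_matrix(ds$alignments$COI)
        prof <- suppressWarnings(motu_sweep(dm))
        outs <- list(species_tsv = file.path(outdir, "species.tsv"),
                     species_json = file.path(outdir, "species.json"),
                     motu = file.path(outdir, "motu_coi.tsv"),
                     sisters = file.path(outdir, "sister_pairs.tsv"))
        write_species_hypotheses(hyp, outs$species_tsv, outs$species_json)
        write_motu_tsv(prof, outs$motu)
        sis <- cross_continent_sisters(ds, hyp)
        write.table(sis, outs$sisters, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        manifest <- record_stage(manifest, stage, in_hash, outs,
                                 cfg$delimit, seed)
        log_msg("delimit: ", nrow(hyp), " species hypotheses, ",
                nrow(sis), " sister pairs", log_json = log_json)
      },
      codiverge = {
        sis_path <- file.path(outdir, "sister_pairs.tsv")
        if (!file.exists(sis_path))
          stop("missing upstream output: ", sis_path,
               "\nrun the delimit stage first", call. = FALSE)
        in_hash <- c(hash_files(c(sis_path,
                                  file.path(datadir, "coi.fasta"))),
                     list(config = as.character(
                       jsonlite::toJSON(cfg$codiverge, auto_unbox = TRUE))))
        if (stage_current(manifest, stage, in_hash)) {
          log_msg("codiverge: up to date, skipped", log_json = log_json)
          next
        }
        ds <- load_dataset_files(datadir)
        hyp_df <- read.delim(file.path(outdir, "species.tsv"),
                             stringsAsFactors = FALSE)
        sis <- read.delim(sis_path, stringsAsFactors = FALSE)
        sis <- sis[sis$n_cn >= 2 & sis$n_aus >= 2, , drop = FALSE]
        if (!nrow(sis))
          stop("no sister pair has two COI sequences per side",
               call. = FALSE)
        coi <- ds$alignments$COI
        members_of <- function(sp)
          intersect(strsplit(hyp_df$members[hyp_df$species_id == sp],
                             ",")[[1]], rownames(coi))
        observed <- lapply(seq_len(nrow(sis)), function(i)
          list(a = coi[members_of(sis$species_cn[i]), , drop = FALSE],
               b = coi[members_of(sis$species_aus[i]), , drop = FALSE]))
        pairs <- data.frame(pair_id = sis$genus,
                            guild = hyp_df$guild[match(sis$species_cn,
                                                       hyp_df$species_id)],
                            n_a = sis$n_cn, n_b = sis$n_aus,
                            stringsAsFactors = FALSE)
        rows <- list()
        for (sc in cfg$codiverge$scenarios) {
          post <- habc_reject(observed, pairs, sc,
                              n_sims = cfg$codiverge$n_sims,
                              keep_fraction = cfg$codiverge$keep_fraction,
                              seed = seed + round(sc), L = ncol(coi),
                              tau_max = cfg$codiverge$tau_max,
                              theta_max = cfg$codiverge$theta_max)
          tab <- evaluate_guild_models(post, seed = seed + round(sc))
          est <- mean_divergence_time(post)
          tab$mean_tau_Ma <- est$estimate_Ma
          tab$sd_tau_Ma <- est$sd_Ma
          rows[[length(rows) + 1L]] <- tab
        }
        res_tab <- do.call(rbind, rows)
        outs <- list(models = file.path(outdir, "divergence_models.tsv"))
        write.table(res_tab, outs$models, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        manifest <- record_stage(manifest, stage, in_hash, outs,
                                 cfg$codiverge, seed)
        log_msg("codiverge: ", nrow(res_tab), " model rows over ",
                length(cfg$codiverge$scenarios), " scenarios",
                log_json = log_json)
      },
      date = {
        sis_path <- file.path(outdir, "sister_pairs.tsv")
        if (!file.exists(sis_path))
          stop("missing upstream output: ", sis_path,
               "\nrun the delimit stage first", call. = FALSE)
        in_hash <- c(hash_files(c(sis_path,
                                  file.path(datadir, "coi.fasta"))),
                     list(config = as.character(
                       jsonlite::toJSON(cfg$date, auto_unbox = TRUE))))
        if (stage_current(manifest, stage, in_hash)) {
          log_msg("date: up to date, skipped", log_json = log_json)
          next
        }
        ds <- load_dataset_files(datadir)
        hyp_df <- read.delim(file.path(outdir, "species.tsv"),
                             stringsAsFactors = FALSE)
        sis <- read.delim(sis_path, stringsAsFactors = FALSE)
        ck <- clock_config(cfg$date$rate, cfg$date$correction)
        dates <- date_sister_pairs(ds, sis, hyp_df, ck,
                                   n_boot = cfg$date$n_boot, seed = seed)
        outs <- list(dates = file.path(outdir, "split_dates.tsv"))
        write.table(dates, outs$dates, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        manifest <- record_stage(manifest, stage, in_hash, outs,
                                 cfg$date, seed)
        log_msg("date: ", nrow(dates), " pairs dated", log_json = log_json)
      },
      compare = {
        sp_path <- file.path(outdir, "species.tsv")
        if (!file.exists(sp_path))
          stop("missing upstream output: ", sp_path,
               "\nrun the delimit stage first", call. = FALSE)
        in_hash <- hash_files(sp_path)
        if (stage_current(manifest, stage, in_hash)) {
          log_msg("compare: up to date, skipped", log_json = log_json)
          next
        }
        ds <- load_dataset_files(datadir)
        hyp <- delimit_species(ds, cfg$delimit$coi_threshold,
                               cfg$delimit$its2_threshold)
        tab <- community_table(hyp, ds)
        cmp <- compare_communities(tab, hyp)
        outs <- list(table_tsv = file.path(outdir, "community.tsv"),
                     table_md = file.path(outdir, "community.md"),
                     comparison = file.path(outdir, "comparison.json"))
        write_community_table(tab, outs$table_tsv, outs$table_md)
        writeLines(jsonlite::toJSON(unclass(cmp), auto_unbox = TRUE,
                                    pretty = TRUE, digits = NA),
                   outs$comparison)
        manifest <- record_stage(manifest, stage, in_hash, outs,
                                 list(), seed)
        log_msg("compare: ", cmp$shared_genera$count, " shared genera",
                log_json = log_json)
      })
    write_manifest(outdir, manifest)
  }
  invisible(read_manifest(outdir))
}
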