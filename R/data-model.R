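# Reading, validating and joining marker alignments and sample metadata.

.MARKERS <- c("COI", "ITS2")

normalize_residues <- function(x) {
  x <- toupper(x)
  x[x == "U"] <- "T"
  x
}

#' Construct a marker alignment from a character matrix
#'
#' @param mat character matrix, rows = samples (rownames = sample ids),
#'   columns = alignment positions; residues over `A,C,G,T,-,N`
#'   (case-insensitive, `U` accepted and mapped to `T`).
#' @param marker `"COI"` or `"ITS2"`.
#' @return An object of class `marker_alignment`: the normalized matrix
#'   with attributes `marker` and implied `length = ncol`.
#' @export
marker_alignment <- function(mat, marker) {
  marker <- match.arg(marker, .MARKERS)
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L)
    stop("empty alignment for marker ", marker, call. = FALSE)
  ids <- rownames(mat)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must carry a non-empty sample id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in ", marker, " alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mat[] <- normalize_residues(mat)
  bad <- !(mat %in% .ALPHABET)
  if (any(bad)) {
    chars <- unique(mat[bad])
    stop("disallowed residue(s) in ", marker, " alignment: ",
         paste(chars, collapse = ", "),
         " (IUPAC ambiguity codes other than N are rejected)", call. = FALSE)
  }
  structure(mat, marker = marker, class = c("marker_alignment", "matrix", "array"))
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("<marker_alignment> ", attr(x, "marker"), ": ", nrow(x),
      " sequences x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file as a marker alignment
#'
#' Sequences must all have the same length (it is an alignment, not raw
#' reads); ragged input, duplicate ids and empty files are errors.  Input
#' order is preserved.
#'
#' @param path path to an aligned FASTA file.
#' @param marker `"COI"` or `"ITS2"`.
#' @return A [marker_alignment()].
#' @export
read_fasta_alignment <- function(path, marker) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(seqs) || length(seqs) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged sequence lengths in ", path, ": ",
         paste(sort(unique(lens)), collapse = ", "),
         " (input must be aligned)", call. = FALSE)
  mat <- toupper(as.character(as.matrix(seqs)))
  marker_alignment(mat, marker)
}

#' Write a marker alignment as FASTA
#'
#' @param aln a [marker_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read the sample metadata table
#'
#' Expects a TSV with header columns `sample_id`, `genus`, `region`,
#' `guild` and optionally `species_label`.  Region values are passed
#' through [normalize_region()]; guild values must be one of the five
#' labels in [GUILDS]; a genus must map to a single guild throughout the
#' table.
#'
#' @param path path to the TSV file.
#' @return A data.frame of validated wasp records, class `wasp_metadata`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  wasp_metadata(df)
}

#' Validate a data.frame of wasp sample records
#'
#' @param df data.frame with columns `sample_id`, `genus`, `region`,
#'   `guild` and optionally `species_label`.
#' @return The validated data.frame, class `wasp_metadata`.
#' @export
wasp_metadata <- function(df) {
  req <- c("sample_id", "genus", "region", "guild")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (any(!nzchar(df$sample_id))) stop("empty sample_id", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  df$region <- normalize_region(df$region)
  df$guild <- as.character(df$guild)
  bad <- setdiff(unique(df$guild), GUILDS)
  if (length(bad))
    stop("unknown guild value(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(GUILDS, collapse = ", "), ")",
         call. = FALSE)
  gg <- unique(df[, c("genus", "guild")])
  dup <- gg$genus[duplicated(gg$genus)]
  if (length(dup))
    stop("genus mapped to more than one guild: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!"species_label" %in% names(df)) df$species_label <- NA_character_
  rownames(df) <- NULL
  class(df) <- c("wasp_metadata", "data.frame")
  df
}

#' Join marker alignments and metadata into a community dataset
#'
#' Every sequence id must have a metadata row; a sample may legitimately
#' be present for only one marker (amplification failures are part of the
#' data model), and the per-marker coverage is reported.
#'
#' @param alignments named list of [marker_alignment()] objects (names
#'   `COI` and/or `ITS2`).
#' @param metadata a `wasp_metadata` data.frame (see [read_metadata()]).
#' @return An object of class `community_dataset`: list with elements
#'   `alignments`, `metadata`, and `summary` (per-marker counts and ids
#'   missing each marker).
#' @export
build_dataset <- function(alignments, metadata) {
  metadata <- wasp_metadata(as.data.frame(metadata))
  if (is.null(names(alignments)) || !all(names(alignments) %in% .MARKERS))
    stop("alignments must be a named list over markers ",
         paste(.MARKERS, collapse = "/"), call. = FALSE)
  for (m in names(alignments)) {
    orphans <- setdiff(rownames(alignments[[m]]), metadata$sample_id)
    if (length(orphans))
      stop("sequence id(s) in ", m, " alignment absent from metadata: ",
           paste(orphans, collapse = ", "), call. = FALSE)
  }
  # stable sample order regardless of input row order
  metadata <- metadata[order(metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  per_marker <- lapply(setNames(.MARKERS, .MARKERS), function(m) {
    if (is.null(alignments[[m]])) character(0) else sort(rownames(alignments[[m]]))
  })
  missing <- lapply(per_marker, function(ids) setdiff(metadata$sample_id, ids))
  summary <- list(
    n_samples = nrow(metadata),
    n_per_marker = vapply(per_marker, length, integer(1)),
    missing_marker = missing
  )
  structure(list(alignments = alignments[intersect(.MARKERS, names(alignments))],
                 metadata = metadata, summary = summary),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  s <- x$summary
  cat("<community_dataset> ", s$n_samples, " samples; ",
      paste(names(s$n_per_marker), s$n_per_marker, sep = "=", collapse = ", "),
      "\n", sep = "")
  for (m in names(s$missing_marker)) {
    n <- length(s$missing_marker[[m]])
    if (n) cat("  missing ", m, ": ", n, " sample(s)\n", sep = "")
  }
  invisible(x)
}

#' Summarize a community dataset as JSON
#'
#' @param dataset a `community_dataset`.
#' @param path optional output path; if `NULL`, the JSON string is
#'   returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
dataset_summary_json <- function(dataset, path = NULL) {
  s <- dataset$summary
  obj <- list(n_samples = s$n_samples,
              n_per_marker = as.list(s$n_per_marker),
              missing_marker = s$missing_marker,
              genera = table_to_list(table(dataset$metadata$genus)),
              regions = table_to_list(table(dataset$metadata$region)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

table_to_list <- function(tb) as.list(setNames(as.integer(tb), names(tb)))
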