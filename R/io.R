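#' Read a differential-expression result table
#'
#' Expects a tab-separated file with header columns `gene_id`, `log2fc`,
#' `adj_p` (one row per gene; how multi-probe genes were collapsed upstream is
#' the caller's responsibility).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `gene_id` (character), `log2fc`
#'   (numeric), `adj_p` (numeric).
#' @export
read_de_table <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  need <- c("gene_id", "log2fc", "adj_p")
  if (!all(need %in% names(x))) {
    stop("DE table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  x$gene_id <- as.character(x$gene_id)
  x$log2fc <- as.numeric(x$log2fc)
  x$adj_p <- as.numeric(x$adj_p)
  x[need]
}

#' Read a directory of differential-expression tables into long format
#'
#' @param paths Named character vector of file paths; names are used as
#'   dataset ids (defaults to file base names without extension).
#' @return Long data.frame with columns `gene_id`, `dataset_id`, `log2fc`,
#'   `adj_p`.
#' @export
read_de_tables <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  out <- lapply(names(paths), function(id) {
    x <- read_de_table(paths[[id]])
    x$dataset_id <- id
    x
  })
  do.call(rbind, out)[, c("gene_id", "dataset_id", "log2fc", "adj_p")]
}

#' Read a dataset configuration table
#'
#' Expression dataset configs carry `dataset_id`, `study_id` and optional
#' per-dataset threshold overrides `lfc_min`, `p_max` (NA means package
#' default). ChIP dataset configs carry `dataset_id`, `study_id`, `factor`,
#' `species`.
#'
#' @param path Path to a TSV file with a `dataset_id` column.
#' @return A data.frame, one row per dataset.
#' @export
read_dataset_config <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  if (!"dataset_id" %in% names(x)) {
    stop("dataset config ", path, " must have a dataset_id column")
  }
  if (anyDuplicated(x$dataset_id)) {
    stop("dataset config ", path, " has duplicated dataset_id values")
  }
  x
}

#' Read a BED file of ChIP peaks
#'
#' @param path Path to a BED file (0-based half-open, as per the BED
#'   standard).
#' @param dataset_id Optional dataset id stored in the `dataset_id` metadata
#'   column.
#' @return A [GenomicRanges::GRanges] (1-based, closed intervals).
#' @export
read_peak_bed <- function(path, dataset_id = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(dataset_id)) mcols(gr)$dataset_id <- dataset_id
  gr
}

#' Read several peak BED files into one GRanges tagged by dataset
#'
#' @param paths Named character vector of BED paths; names are dataset ids.
#' @return A [GenomicRanges::GRanges] with a `dataset_id` metadata column.
#' @export
read_peak_beds <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  grs <- lapply(names(paths), function(id) read_peak_bed(paths[[id]], id))
  do.call(c, grs)
}

#' Read a TSS annotation table
#'
#' @param path TSV with header `gene_id`, `chrom`, `tss`, `strand`; `tss` is
#'   the 1-based coordinate of the transcription start base.
#' @return data.frame with those columns.
#' @export
read_annotation <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(x))) {
    stop("annotation ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  x$tss <- as.integer(x$tss)
  x[need]
}

#' Read an orthology table
#'
#' @param path TSV with header `gene_A`, `gene_B`, `homology_type`;
#'   one-to-one rows carry the type `"one2one"`.
#' @return data.frame with those columns.
#' @export
read_orthology <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  need <- c("gene_A", "gene_B", "homology_type")
  if (!all(need %in% names(x))) {
    stop("orthology table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  x[need]
}

#' Read a bedGraph conservation track
#'
#' @param path Path to a bedGraph file.
#' @return A [GenomicRanges::GRanges] with a numeric `score` column.
#' @export
read_bedgraph_track <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; names are set ids, the
#'   `description` attribute keeps the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @param header_comment Optional character vector written as leading
#'   `#`-prefixed lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GRanges -> BED-style data.frame (0-based half-open), used by fixture writers.
granges_to_bed_df <- function(gr, score = NULL, name = NULL) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(name)) df$name <- name
  if (!is.null(score)) {
    if (is.null(df$name)) df$name <- "."
    df$score <- score
  }
  df
}

write_bed <- function(gr, path, score = NULL, name = NULL) {
  df <- granges_to_bed_df(gr, score = score, name = name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
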