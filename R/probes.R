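#' Construct a probe set
#'
#' A probe set is the ordered 1-D axis the window scan slides over: CpG
#' probes sorted by (chromosome, position), with a dense 0-based `index`
#' within each chromosome. Positions are 1-based and must be unique within a
#' chromosome; duplicated positions are collapsed to the first probe with a
#' warning.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based basepair coordinates.
#' @return A `data.frame` of class `probe_set` with columns `probe_id`,
#'   `chrom`, `pos`, `index`, sorted by (chrom, pos).
#' @export
probe_set <- function(probe_id, chrom, pos) {
  stopifnot(length(probe_id) == length(chrom), length(chrom) == length(pos))
  if (length(probe_id) == 0L) stop("probe set is empty")
  probe_id <- as.character(probe_id)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (anyNA(pos) || any(pos < 1L)) stop("probe positions must be positive integers")
  if (anyDuplicated(probe_id)) {
    stop("duplicated probe_id: ", paste(unique(probe_id[duplicated(probe_id)])[1:min(3, sum(duplicated(probe_id)))], collapse = ", "))
  }
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    warning(sum(dup), " probe(s) at duplicated positions collapsed to one probe per position")
    probe_id <- probe_id[!dup]; chrom <- chrom[!dup]; pos <- pos[!dup]
  }
  o <- order(chrom, pos)
  ps <- data.frame(probe_id = probe_id[o], chrom = chrom[o], pos = pos[o],
                   stringsAsFactors = FALSE)
  ps$index <- stats::ave(seq_len(nrow(ps)), ps$chrom, FUN = seq_along) - 1L
  class(ps) <- c("probe_set", "data.frame")
  ps
}

#' Read a probe manifest
#'
#' Accepts a TSV with columns `probe_id`, `chrom`, `pos` (header required), or
#' a headerless 3/4-column BED file (`chrom start end [name]`; the 0-based BED
#' start is converted to a 1-based position). Gzipped input is handled
#' transparently.
#'
#' @param path path to manifest file (TSV or BED; optionally gzipped).
#' @return a [probe_set()].
#' @export
read_probe_manifest <- function(path) {
  ln <- readLines(path, n = 1L)
  if (length(ln) == 0L) stop("empty probe manifest: ", path)
  fields <- strsplit(ln, "\t")[[1]]
  if (all(c("probe_id", "chrom", "pos") %in% fields)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "")
    if (anyNA(suppressWarnings(as.integer(tab$pos)))) {
      bad <- which(is.na(suppressWarnings(as.integer(tab$pos))))[1]
      stop("malformed pos at line ", bad + 1L, " of ", path)
    }
    probe_set(tab$probe_id, tab$chrom, as.integer(tab$pos))
  } else if (length(fields) %in% c(3L, 4L) && !is.na(suppressWarnings(as.integer(fields[2])))) {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "")
    ids <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
      paste0(tab[[1]], ":", tab[[2]] + 1L)
    probe_set(ids, tab[[1]], as.integer(tab[[2]]) + 1L)
  } else {
    stop("unrecognized manifest format (need probe_id/chrom/pos TSV or 3/4-column BED): ", path)
  }
}

#' Read a beta-value matrix
#'
#' TSV with probe ids in the first column and one numeric column per sample.
#' Rows are reordered to match the probe set; probes present in the manifest
#' but absent from the matrix are an error, matrix rows absent from the
#' manifest are dropped with a message.
#'
#' @param path TSV file (optionally gzipped), first column probe ids.
#' @param probes a [probe_set()].
#' @return numeric matrix with `rownames` = probe ids in probe-set order and
#'   `colnames` = sample ids; all values in \[0, 1\].
#' @export
read_beta_matrix <- function(path, probes) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  extra <- setdiff(rownames(m), probes$probe_id)
  if (length(extra)) {
    message(length(extra), " matrix probe(s) absent from manifest dropped")
    m <- m[!rownames(m) %in% extra, , drop = FALSE]
  }
  missing <- setdiff(probes$probe_id, rownames(m))
  if (length(missing)) {
    stop("manifest probe(s) missing from beta matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  m <- m[probes$probe_id, , drop = FALSE]
  validate_beta(m)
  m
}

validate_beta <- function(m) {
  bad <- which(is.na(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta value out of [0,1] (or non-numeric) at probe ",
         rownames(m)[bad[1, 1]], ", sample ", colnames(m)[bad[1, 2]])
  }
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids in beta matrix")
  invisible(m)
}

#' Read a sample sheet
#'
#' CSV or TSV with columns `sample_id` and `group`. Exactly two groups, each
#' with at least two samples, are required by the testing operations.
#'
#' @param path sample sheet file.
#' @return data.frame with character columns `sample_id` and `group`.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab))) {
    stop("sample sheet needs columns sample_id, group: ", path)
  }
  data.frame(sample_id = as.character(tab$sample_id),
             group = as.character(tab$group), stringsAsFactors = FALSE)
}

#' Filter probes and the beta matrix consistently
#'
#' Removes probes by id (e.g. SNP-overlapping probes) and/or whole
#' chromosomes (e.g. sex chromosomes) from both the probe set and the beta
#' matrix, then re-densifies the per-chromosome index.
#'
#' @param probes a [probe_set()].
#' @param beta beta matrix aligned to `probes` (or `NULL`).
#' @param exclude_ids probe ids to drop; unknown ids are ignored with a message.
#' @param exclude_chroms chromosome names to drop.
#' @return list with elements `probes` and `beta`.
#' @export
filter_probes <- function(probes, beta = NULL, exclude_ids = character(),
                          exclude_chroms = character()) {
  unknown <- setdiff(exclude_ids, probes$probe_id)
  if (length(unknown)) message(length(unknown), " unknown exclude id(s) ignored")
  keep <- !(probes$probe_id %in% exclude_ids) & !(probes$chrom %in% exclude_chroms)
  if (!any(keep)) message("all probes removed by filters")
  ps <- probes[keep, , drop = FALSE]
  ps$index <- stats::ave(seq_len(nrow(ps)), ps$chrom, FUN = seq_along) - 1L
  class(ps) <- c("probe_set", "data.frame")
  list(probes = ps,
       beta = if (is.null(beta)) NULL else beta[keep, , drop = FALSE])
}

#' Write called DMRs as BED and TSV
#'
#' The BED file is 0-based half-open with `name = layer:rank` and
#' `score = -log10(p_adjusted)` capped at 1000; the TSV carries every region
#' field (1-based inclusive coordinates). Both are sorted by (chrom, start).
#'
#' @param dmrs data.frame of regions as produced by [dmrscale()] layers, with
#'   columns `chrom, start, end, first_index, last_index, n_cpgs, p_region,
#'   log10_p_region, p_adjusted, layer, mean_delta_beta`.
#' @param path_bed,path_table output paths; either may be `NULL` to skip.
#' @return invisibly, the sorted data.frame written to the TSV.
#' @export
write_dmrs <- function(dmrs, path_bed = NULL, path_table = NULL) {
  cols <- c("chrom", "start", "end", "first_index", "last_index", "n_cpgs",
            "p_region", "log10_p_region", "p_adjusted", "layer",
            "mean_delta_beta")
  if (nrow(dmrs) == 0L) {
    dmrs <- empty_dmr_frame()
  }
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start), cols, drop = FALSE]
  if (!is.null(path_bed)) {
    if (nrow(dmrs) == 0L) {
      writeLines(character(0), path_bed)
    } else {
      score <- pmin(1000, round(-log10(pmax(dmrs$p_adjusted, 1e-1000)), 3))
      # recover magnitudes below double range from the log-scale column
      deep <- dmrs$p_adjusted <= .Machine$double.xmin & dmrs$log10_p_region < -300
      score[deep] <- 1000
      bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                        end = dmrs$end,
                        name = paste0(dmrs$layer, ":", seq_len(nrow(dmrs))),
                        score = score)
      utils::write.table(bed, path_bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  if (!is.null(path_table)) {
    utils::write.table(dmrs, path_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dmrs)
}

empty_dmr_frame <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             first_index = integer(), last_index = integer(),
             n_cpgs = integer(), p_region = double(),
             log10_p_region = double(), p_adjusted = double(),
             layer = integer(), mean_delta_beta = double(),
             stringsAsFactors = FALSE)
}

#' Read intervals from a BED file
#'
#' Minimal BED reader for truth sets, called-DMR sets from any caller, and
#' gene annotation. Coordinates are converted to the package's internal
#' 1-based inclusive convention.
#'
#' @param path BED file (>= 3 columns; optional name in column 4, score in 5).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive) and,
#'   when present, `name` and `score`.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]) + 1L,
                    end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  if (ncol(tab) >= 5) out$score <- suppressWarnings(as.numeric(tab[[5]]))
  out
}

# 1-based inclusive region data.frame -> GRanges
regions_to_granges <- function(r) {
  GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
}
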