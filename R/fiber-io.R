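## Fiber-table TSV: a plain-text per-molecule exchange format.
##
## Line 1 is the versioned header "#dichrom_fiber_table_v1", line 2 the
## column header. Columns: fiber_id, chrom, start, end, then comma-joined
## lists m6a, nuc_starts, nuc_lens, msp_starts, msp_lens, cpg_pos,
## cpg_meth (0/1). Empty lists are written as ".".

FIBER_TABLE_VERSION <- "dichrom_fiber_table_v1"

.join_list <- function(x) if (length(x)) paste(x, collapse = ",") else "."

.split_list <- function(s) {
  if (is.na(s) || s == "." || s == "") return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
}

#' Read a fiber-table TSV
#'
#' @param path Path to a fiber-table file (see format notes in the package
#'   source; written by [write_fiber_table()]).
#' @param schema Expected schema tag; only `"dichrom_fiber_table_v1"` is
#'   understood.
#' @return List of [fiber()] objects. Rows that violate the `Fiber`
#'   invariants abort with an error naming the offending row / fiber.
#' @export
read_fiber_table <- function(path, schema = FIBER_TABLE_VERSION) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!identical(sub("^#", "", first), schema)) {
    stop("fiber table ", path, ": expected schema '", schema,
         "', found '", first, "'")
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                         colClasses = "character", comment.char = "")
  need <- c("fiber_id", "chrom", "start", "end", "m6a", "nuc_starts",
            "nuc_lens", "msp_starts", "msp_lens", "cpg_pos", "cpg_meth")
  if (!all(need %in% names(d))) {
    stop("fiber table ", path, ": missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  out <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    start <- suppressWarnings(as.integer(row$start))
    end <- suppressWarnings(as.integer(row$end))
    if (is.na(start) || is.na(end)) {
      stop("fiber table ", path, ", row ", i, ": malformed coordinates")
    }
    ns <- .split_list(row$nuc_starts); nl <- .split_list(row$nuc_lens)
    ms <- .split_list(row$msp_starts); ml <- .split_list(row$msp_lens)
    if (length(ns) != length(nl) || length(ms) != length(ml)) {
      stop("fiber table ", path, ", row ", i,
           ": start/length list lengths differ")
    }
    cp <- .split_list(row$cpg_pos); cm <- .split_list(row$cpg_meth)
    if (length(cp) != length(cm)) {
      stop("fiber table ", path, ", row ", i, ": cpg list lengths differ")
    }
    out[[i]] <- tryCatch(
      fiber(row$fiber_id, row$chrom, start, end,
            m6a = .split_list(row$m6a),
            nucleosomes = iv_matrix(ns, ns + nl),
            msps = iv_matrix(ms, ms + ml),
            cpg = data.frame(pos = cp, meth = cm == 1L)),
      error = function(e) {
        stop("fiber table ", path, ", row ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  out
}

#' Write fibers to a fiber-table TSV
#'
#' @param fibers List of `Fiber` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(fibers, path) {
  rows <- vapply(fibers, function(f) {
    paste(f$fiber_id, f$chrom, f$start, f$end,
          .join_list(f$m6a),
          .join_list(f$nucleosomes[, "start"]),
          .join_list(f$nucleosomes[, "end"] - f$nucleosomes[, "start"]),
          .join_list(f$msps[, "start"]),
          .join_list(f$msps[, "end"] - f$msps[, "start"]),
          .join_list(f$cpg$pos),
          .join_list(as.integer(f$cpg$meth)),
          sep = "\t")
  }, character(1))
  writeLines(c(paste0("#", FIBER_TABLE_VERSION),
               paste("fiber_id", "chrom", "start", "end", "m6a",
                     "nuc_starts", "nuc_lens", "msp_starts", "msp_lens",
                     "cpg_pos", "cpg_meth", sep = "\t"),
               rows), path)
  invisible(path)
}

#' Read a satellite annotation BED
#'
#' BED4 with the satellite class in column 4. Unknown class labels are
#' mapped to `other_satellite` with a warning.
#'
#' @param path BED file path.
#' @return A [satellite_annotation()] table.
#' @export
read_satellite_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  cls <- as.character(gr$name)
  known <- c("active_hor", "inactive_hor", "divergent_monomeric",
             "other_satellite", "non_satellite")
  if (any(!cls %in% known)) {
    warning("unknown satellite classes mapped to other_satellite: ",
            paste(unique(cls[!cls %in% known]), collapse = ", "))
    cls[!cls %in% known] <- "other_satellite"
  }
  satellite_annotation(as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr), cls)
}

#' Write intervals as BED
#'
#' @param intervals List of `GenomicInterval`s, or a data frame with
#'   columns `chrom`, `start`, `end` and optionally `name`, `score`,
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (is.data.frame(intervals)) {
    d <- intervals
  } else {
    d <- data.frame(
      chrom = vapply(intervals, `[[`, character(1), "chrom"),
      start = vapply(intervals, `[[`, integer(1), "start"),
      end = vapply(intervals, `[[`, integer(1), "end"),
      name = vapply(intervals, function(x)
        if (is.null(x$name)) "." else x$name, character(1)),
      score = 0L,
      strand = vapply(intervals, `[[`, character(1), "strand"))
  }
  gr <- GenomicRanges::GRanges(
    d$chrom,
    IRanges::IRanges(d$start + 1L, d$end),
    strand = if ("strand" %in% names(d)) S4Vectors_strand(d$strand) else "*")
  if ("name" %in% names(d)) gr$name <- d$name
  if ("score" %in% names(d)) gr$score <- as.numeric(d$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

S4Vectors_strand <- function(s) {
  s[is.na(s) | s == "."] <- "*"
  s
}

#' Write a density or methylation track as bedGraph
#'
#' Positions with undefined values (zero coverage) are omitted, matching
#' the sparse bedGraph convention.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start of the per-bp value vector.
#' @param values Numeric vector, one value per bp; `NA` = undefined.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(chrom, start, values, path) {
  n <- length(values)
  keep <- !is.na(values)
  if (!any(keep)) { writeLines(character(0), path); return(invisible(path)) }
  ## run-length encode to keep files small
  r <- rle(ifelse(keep, values, NA))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  ok <- !is.na(r$values)
  d <- data.frame(chrom = chrom, start = start + starts[ok],
                  end = start + ends[ok], value = r$values[ok])
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA path.
#' @return A named `DNAStringSet`.
#' @export
read_reference <- function(path) {
  Biostrings::readDNAStringSet(path)
}
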