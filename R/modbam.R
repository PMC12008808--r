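## Modified-base BAM consumption (MM/ML dialect).
##
## The package does not call modifications from kinetics; it consumes
## base-modification tags written upstream (m6A as A+a, 5mCpG as C+m) and
## lifts query-space calls to reference coordinates through the CIGAR.
## Per-read footprint interval tags (ns/nl for protected footprints,
## as/al for MTase-sensitive patches, in original-read coordinates) are
## read when present; otherwise footprint slots are left empty.

## per-query-base (1-based index) -> 0-based reference position; NA for
## insertions and clips
.cigar_query_to_ref <- function(cigar, pos0) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  qlen <- sum(lens[ops %in% c("M", "I", "S", "=", "X")])
  map <- rep(NA_integer_, qlen)
  q <- 0L; r <- pos0
  for (i in seq_along(ops)) {
    op <- ops[i]; n <- lens[i]
    if (op %in% c("M", "=", "X")) {
      map[(q + 1L):(q + n)] <- r + 0L:(n - 1L)
      q <- q + n; r <- r + n
    } else if (op %in% c("I", "S")) {
      q <- q + n
    } else if (op %in% c("D", "N")) {
      r <- r + n
    }
  }
  map
}

## Parse one read's MM/ML into a data frame (base, code, qpos0 in stored
## orientation, prob). qpos0 is the 0-based index into the stored SEQ.
.parse_mm <- function(mm, ml, seq_stored, reversed) {
  mm <- sub(";$", "", mm)
  if (!nzchar(mm)) return(NULL)
  entries <- strsplit(mm, ";", fixed = TRUE)[[1L]]
  seq_orig <- if (reversed) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_stored)))
  } else seq_stored
  orig_chars <- strsplit(seq_orig, "")[[1L]]
  L <- length(orig_chars)
  out <- list(); ml_used <- 0L
  for (ent in entries) {
    parts <- strsplit(ent, ",", fixed = TRUE)[[1L]]
    head <- parts[1L]
    deltas <- as.integer(parts[-1L])
    base <- substr(head, 1L, 1L)
    code <- sub("^[ACGTUN][-+]", "", head)
    code <- sub("[.?]$", "", code)
    n <- length(deltas)
    probs <- if (n) (ml[(ml_used + 1L):(ml_used + n)]) / 255 else numeric(0)
    ml_used <- ml_used + n
    if (!n) next
    hits <- which(orig_chars == base)
    idx <- cumsum(deltas + 1L)   # ranks among base occurrences
    if (max(idx) > length(hits)) {
      stop("MM tag indexes more ", base, " bases than the read contains")
    }
    opos0 <- hits[idx] - 1L      # 0-based, original orientation
    qpos0 <- if (reversed) L - 1L - opos0 else opos0
    out[[length(out) + 1L]] <- data.frame(
      base = base, code = code, qpos0 = qpos0, prob = probs)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## lift footprint start/length tag pairs (original-read coordinates) to
## reference interval matrices
.lift_footprints <- function(starts, lens, map, L, reversed) {
  if (is.null(starts) || !length(starts)) return(iv_matrix())
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)) {
    o1 <- starts[i]; o2 <- starts[i] + lens[i] - 1L   # inclusive, original
    if (reversed) { tmp <- L - 1L - o2; o2 <- L - 1L - o1; o1 <- tmp }
    rr <- map[(o1 + 1L):(o2 + 1L)]
    rr <- rr[!is.na(rr)]
    if (length(rr) < 2L) next
    out_s <- c(out_s, min(rr)); out_e <- c(out_e, max(rr) + 1L)
  }
  iv_matrix(out_s, out_e)
}

#' Read fibers from a modified-base BAM
#'
#' Converts MM/ML base-modification calls into per-fiber m6A events and
#' CpG methylation calls in reference coordinates. A modification call
#' becomes an event when its scaled probability (ML/255) is at least the
#' threshold. CpG calls are trinary: methylated when `prob >=
#' cpg_prob_threshold`, unmethylated when `prob <= 1 - cpg_prob_threshold`,
#' otherwise not called. Insertions are skipped; deletions emit nothing.
#'
#' @param path Coordinate-sorted, indexed BAM with MM/ML tags.
#' @param m6a_prob_threshold,cpg_prob_threshold Probability cutoffs in
#'   `[0, 1]` (default 0.8).
#' @return List of [fiber()] objects. Unmapped reads are skipped with a
#'   message giving the count.
#' @export
read_modbam <- function(path, m6a_prob_threshold = 0.8,
                        cpg_prob_threshold = 0.8) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MM", "ML", "Mm", "Ml", "ns", "nl", "as", "al"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  n <- length(b$qname)
  if (!n) return(list())
  unmapped <- bitwAnd(b$flag, 4L) != 0L | is.na(b$pos)
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped read(s) skipped")
  }
  tag <- b$tag
  get_tag <- function(nm, i) if (is.null(tag[[nm]])) NULL else tag[[nm]][[i]]
  have_mm <- !is.null(tag$MM) || !is.null(tag$Mm)
  if (!have_mm) stop("BAM ", path, " carries no MM/Mm base-modification tag")
  out <- list()
  for (i in seq_len(n)) {
    if (unmapped[i]) next
    mm <- get_tag("MM", i); if (is.null(mm) || is.na(mm)) mm <- get_tag("Mm", i)
    ml <- get_tag("ML", i); if (is.null(ml)) ml <- get_tag("Ml", i)
    if (is.null(mm) || is.na(mm)) {
      stop("read ", b$qname[i], " lacks an MM tag")
    }
    seq_stored <- as.character(b$seq[i])
    reversed <- bitwAnd(b$flag[i], 16L) != 0L
    map <- .cigar_query_to_ref(b$cigar[i], b$pos[i] - 1L)
    L <- nchar(seq_stored)
    calls <- .parse_mm(mm, as.integer(ml), seq_stored, reversed)
    m6a <- integer(0)
    cpg <- data.frame(pos = integer(0), meth = logical(0))
    if (!is.null(calls)) {
      calls$ref <- map[calls$qpos0 + 1L]
      calls <- calls[!is.na(calls$ref), , drop = FALSE]
      a <- calls[calls$base == "A" & calls$code == "a", , drop = FALSE]
      m6a <- sort(unique(a$ref[a$prob >= m6a_prob_threshold]))
      cm <- calls[calls$base == "C" & calls$code == "m", , drop = FALSE]
      is_m <- cm$prob >= cpg_prob_threshold
      is_u <- cm$prob <= 1 - cpg_prob_threshold
      keep <- is_m | is_u
      cpg <- data.frame(pos = cm$ref[keep], meth = is_m[keep])
      cpg <- cpg[!duplicated(cpg$pos), , drop = FALSE]
    }
    mapped <- map[!is.na(map)]
    out[[length(out) + 1L]] <- fiber(
      b$qname[i], as.character(b$rname[i]),
      min(mapped), max(mapped) + 1L, m6a = m6a,
      nucleosomes = .lift_footprints(get_tag("ns", i), get_tag("nl", i),
                                     map, L, reversed),
      msps = .lift_footprints(get_tag("as", i), get_tag("al", i),
                              map, L, reversed),
      cpg = cpg)
  }
  out
}
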