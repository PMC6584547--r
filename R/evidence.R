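#' Log-likelihood of an ungapped alignment under a flat error model
#'
#' Each aligned base is correct with probability `1 - eps` and miscalled to a
#' specific wrong base with probability `eps / 3`, so an alignment with `m`
#' matching and `x` mismatching bases scores
#' `m * log(1 - eps) + x * log(eps / 3)`.
#'
#' @param matches,mismatches Non-negative base counts (vectorised).
#' @param eps Per-base error rate, strictly inside (0, 1).
#' @return Numeric vector of log-likelihoods (always `<= 0`).
#' @examples
#' alignment_loglik(100, 0, 0.01)  # 100 * log(0.99)
#' @export
alignment_loglik <- function(matches, mismatches, eps = 0.01) {
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0 || eps >= 1) {
    stop("eps must lie strictly inside (0, 1)")
  }
  if (any(matches < 0) || any(mismatches < 0)) {
    stop("matches and mismatches must be non-negative")
  }
  matches * log1p(-eps) + mismatches * log(eps / 3)
}

#' Align one read against every panel allele (naive seed-and-extend)
#'
#' A deliberately simple ungapped aligner so that the package is testable
#' without an external mapper: exact k-mer seeds taken at the start, middle
#' and end of the read (both strands) propose diagonals, each fully
#' contained placement is scored by Hamming distance, and the best placement
#' per allele with at most `max_mismatches` mismatches is reported.
#'
#' @param seq Read sequence (a single string).
#' @param panel An `hla_panel`.
#' @param max_mismatches Maximum mismatches tolerated per placement.
#' @param k Seed length; the read must be at least `k` bases long.
#' @return `data.frame` with columns `allele`, `matches`, `mismatches`,
#'   `aligned_length`, `strand` (`+`/`-`), `pos` (0-based placement start);
#'   zero rows when nothing aligns.
#' @export
naive_align <- function(seq, panel, max_mismatches = 6L, k = 21L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) > min(nchar(panel$seq))) {
    stop("read longer than the shortest panel allele")
  }
  hits <- cpp_seed_extend(seq, unname(panel$seq), as.integer(k),
                          as.integer(max_mismatches))
  L <- nchar(seq)
  data.frame(allele = names(panel$seq)[hits$ref],
             matches = L - hits$mismatches,
             mismatches = hits$mismatches,
             aligned_length = rep(L, nrow(hits)),
             strand = c("+", "-")[hits$strand + 1L],
             pos = hits$pos)
}

new_evidence <- function(entries, read_len, alleles, n_dropped = 0L) {
  entries <- entries[order(entries$read, entries$allele), , drop = FALSE]
  rownames(entries) <- NULL
  stopifnot(all(is.finite(entries$log_lik)),
            all(entries$read %in% names(read_len)))
  structure(list(entries = entries,
                 read_len = read_len[sort(unique(entries$read))],
                 alleles = alleles, n_dropped = as.integer(n_dropped)),
            class = "hla_evidence")
}

#' @export
print.hla_evidence <- function(x, ...) {
  cat(sprintf(
    "read-allele evidence: %d fragments x %d alleles, %d entries (%.1f candidates/fragment); %d read(s) dropped\n",
    length(x$read_len), length(x$alleles), nrow(x$entries),
    nrow(x$entries) / max(1L, length(x$read_len)), x$n_dropped))
  invisible(x)
}

#' Build a read-allele evidence matrix with the built-in aligner
#'
#' Aligns every read against the panel with [naive_align()] and converts
#' match/mismatch counts to log-likelihoods via [alignment_loglik()].  Reads
#' with no surviving placement are dropped (their count is kept in the
#' `n_dropped` component).  With `paired = TRUE`, read ids ending in `/1`
#' and `/2` are treated as mates of one fragment: for each allele the mates'
#' log-likelihoods are summed when both align, and a lone mate's
#' contribution is kept as is.
#'
#' @param reads Named character vector of read sequences (names are read
#'   ids), or a `data.frame` with columns `id` and `seq`.
#' @param panel An `hla_panel`.
#' @param eps Per-base error rate for scoring.
#' @param max_mismatches,k Passed to [naive_align()].
#' @param paired Treat `/1`,`/2` id suffixes as mate pairs.
#' @return An object of class `hla_evidence`: sparse entries
#'   (`read`, `allele`, `log_lik`), per-fragment aligned base counts
#'   (`read_len`), and the full allele universe of the panel.
#' @export
align_reads <- function(reads, panel, eps = 0.01, max_mismatches = 6L,
                        k = 21L, paired = FALSE) {
  if (is.data.frame(reads)) reads <- stats::setNames(reads$seq, reads$id)
  stopifnot(length(reads) > 0L, !is.null(names(reads)))
  hits <- cpp_seed_extend(unname(reads), unname(panel$seq), as.integer(k),
                          as.integer(max_mismatches))
  rl <- nchar(reads)[hits$read]
  ent <- data.frame(read = names(reads)[hits$read],
                    allele = names(panel$seq)[hits$ref],
                    log_lik = alignment_loglik(rl - hits$mismatches,
                                               hits$mismatches, eps),
                    bases = rl)
  if (paired) {
    frag <- sub("/[12]$", "", ent$read)
    agg <- stats::aggregate(cbind(log_lik, bases) ~ frag + allele, ent, sum)
    ent <- data.frame(read = agg$frag, allele = agg$allele,
                      log_lik = agg$log_lik, bases = agg$bases)
    ids <- unique(sub("/[12]$", "", names(reads)))
  } else {
    ids <- names(reads)
  }
  read_len <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  if (nrow(ent)) {
    bl <- tapply(ent$bases, ent$read, max)  # fragment bases actually aligned
    read_len[names(bl)] <- as.integer(bl)
  }
  kept <- !is.na(read_len)
  new_evidence(ent[, c("read", "allele", "log_lik")],
               read_len[kept], names(panel$seq), n_dropped = sum(!kept))
}

cigar_query_consumed <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    return(NULL)
  }
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  list(aligned = sum(n[op %in% c("M", "=", "X")]),
       ins = sum(n[op == "I"]),
       del = sum(n[op %in% c("D", "N")]),
       soft = sum(n[op == "S"]),
       qlen = sum(n[op %in% c("M", "=", "X", "I", "S")]))
}

md_mismatches <- function(md) {
  # substitution count from an MD tag: letters outside ^-deletion runs
  toks <- regmatches(md, gregexpr("\\^[A-Z]+|[A-Z]|\\d+", md))[[1]]
  sum(grepl("^[A-Z]$", toks))
}

#' Build the evidence matrix from SAM/BAM alignments against the panel
#'
#' Reads primary and secondary alignments of reads mapped to the panel
#' FASTA.  Substitution counts come from the `NM` tag (minus inserted and
#' deleted bases) when present, else from the `MD` tag; records whose
#' aligned portion covers less than `min_aligned_frac` of the read are
#' dropped, as are unmapped records.  Paired mates aligned to the same
#' allele contribute the sum of their log-likelihoods as a single evidence
#' row for the fragment.
#'
#' @param file Path to a BAM file, or a SAM text file (converted on the
#'   fly).
#' @param panel An `hla_panel`; every alignment target must resolve to a
#'   panel allele (aliases are honoured).
#' @param min_aligned_frac Minimum fraction of the read that must be
#'   aligned (M/=/X plus insertions) for a record to count.
#' @param eps Per-base error rate for scoring.
#' @return An `hla_evidence` object.
#' @export
evidence_from_sam <- function(file, panel, min_aligned_frac = 0.9,
                              eps = 0.01) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar", "seq"),
    tag = c("NM", "MD"))
  b <- Rsamtools::scanBam(file, param = p)[[1]]
  n <- length(b$qname)
  rows <- vector("list", n)
  all_frag <- character(0)
  frag_bases <- numeric(0)
  for (i in seq_len(n)) {
    flag <- b$flag[i]
    qname <- b$qname[i]
    mate <- if (bitwAnd(flag, 64L)) "/1" else if (bitwAnd(flag, 128L)) "/2" else ""
    frag <- qname
    rid <- paste0(qname, mate)
    if (bitwAnd(flag, 4L)) { all_frag <- c(all_frag, frag); next }
    target <- as.character(b$rname[i])
    if (target %in% names(panel$aliases)) target <- panel$aliases[[target]]
    if (!target %in% names(panel$seq)) {
      stop(sprintf("alignment target '%s' is not a panel allele", target))
    }
    cg <- cigar_query_consumed(b$cigar[i])
    if (is.null(cg)) {
      warning(sprintf("skipping record '%s': unparseable CIGAR '%s'",
                      qname, b$cigar[i]))
      next
    }
    qlen <- cg$qlen
    all_frag <- c(all_frag, frag)
    if (cg$aligned + cg$ins < min_aligned_frac * qlen) next
    nm <- b$tag$NM[i]
    if (!is.null(nm) && !is.na(nm)) {
      mm <- nm - cg$ins - cg$del
    } else {
      md <- b$tag$MD[i]
      if (is.null(md) || is.na(md)) {
        warning(sprintf("skipping record '%s': no NM or MD tag", qname))
        next
      }
      mm <- md_mismatches(md)
    }
    mm <- max(0L, mm)
    rows[[i]] <- data.frame(
      frag = frag, mate = rid, allele = target,
      log_lik = alignment_loglik(cg$aligned - mm, mm, eps),
      bases = cg$aligned)
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || !nrow(rows)) stop("no usable alignments in ", file)
  # best placement per mate x allele, then sum mates into one fragment row
  rows <- rows[order(rows$mate, rows$allele, -rows$log_lik), , drop = FALSE]
  rows <- rows[!duplicated(rows[, c("mate", "allele")]), , drop = FALSE]
  agg <- stats::aggregate(cbind(log_lik, bases) ~ frag + allele, rows, sum)
  ent <- data.frame(read = agg$frag, allele = agg$allele,
                    log_lik = agg$log_lik)
  bl <- tapply(agg$bases, agg$frag, max)
  read_len <- stats::setNames(as.integer(bl), names(bl))
  n_dropped <- length(setdiff(unique(all_frag), ent$read))
  new_evidence(ent, read_len, names(panel$seq), n_dropped = n_dropped)
}

#' Write / read an evidence matrix as TSV (columns read, allele, log_lik,
#' bases)
#' @param evidence An `hla_evidence`.
#' @param path Output TSV path.
#' @export
write_evidence <- function(evidence, path) {
  df <- evidence$entries
  df$bases <- evidence$read_len[df$read]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(evidence)
}

#' @rdname write_evidence
#' @param alleles Allele universe (normally the panel's allele names); when
#'   `NULL`, the alleles observed in the file.
#' @export
read_evidence <- function(path, alleles = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(alleles)) alleles <- sort(unique(df$allele))
  rl <- tapply(df$bases, df$read, max)
  new_evidence(df[, c("read", "allele", "log_lik")],
               stats::setNames(as.integer(rl), names(rl)), alleles)
}
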