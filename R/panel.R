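#' Construct a reference allele panel
#'
#' A panel bundles allele sequences with their exon/intron/UTR feature
#' annotations.  Feature coordinates are 0-based half-open on the allele
#' sequence (BED convention).  An allele is "full-length" when its features
#' include introns, i.e. when the panel carries genomic rather than
#' exon-only sequence for it; full-length entries are what lets the caller
#' separate alleles that are identical across their exons.
#'
#' @param seq Named character vector of nucleotide sequences over
#'   \{A,C,G,T,N\}; names must parse as HLA allele names and be unique.
#' @param features `data.frame` with columns `allele`, `kind` (one of
#'   `"exon"`, `"intron"`, `"UTR"`), `ordinal` (positive integer), `start`,
#'   `end` (0-based half-open).
#' @param source Either a single string or a named character vector giving,
#'   per allele, `"base"` (e.g. the IMGT-side reference set) or
#'   `"population"` (a population-specific augmentation panel).
#' @param aliases Named character vector mapping retired duplicate names to
#'   the kept canonical names (filled in by [merge_panels()]).
#' @return An object of class `hla_panel`.
#' @seealso [read_panel()], [merge_panels()], [feature_identity_groups()]
#' @export
hla_panel <- function(seq, features = NULL, source = "base",
                      aliases = character(0)) {
  if (is.null(names(seq)) || anyNA(names(seq)) || !all(nzchar(names(seq)))) {
    stop("panel sequences must be named by allele")
  }
  if (anyDuplicated(names(seq))) {
    stop("duplicate allele names in panel: ",
         paste(unique(names(seq)[duplicated(names(seq))]), collapse = ", "))
  }
  for (nm in names(seq)) parse_hla(nm)  # names must be valid nomenclature
  if (any(!nzchar(seq))) stop("empty allele sequence")
  if (any(grepl("[^ACGTN]", seq))) stop("allele sequences must be over ACGTN")
  if (is.null(features)) {
    features <- data.frame(allele = character(0), kind = character(0),
                           ordinal = integer(0), start = integer(0),
                           end = integer(0))
  }
  features <- as.data.frame(features)[, c("allele", "kind", "ordinal",
                                          "start", "end")]
  features$ordinal <- as.integer(features$ordinal)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (!all(features$kind %in% c("exon", "intron", "UTR"))) {
    stop("feature kind must be exon, intron or UTR")
  }
  if (!all(features$allele %in% names(seq))) {
    stop("features refer to alleles absent from the panel")
  }
  if (any(features$ordinal < 1L)) stop("feature ordinals must be positive")
  lens <- nchar(seq)[features$allele]
  if (any(features$start < 0L) || any(features$start >= features$end) ||
      any(features$end > lens)) {
    stop("feature coordinates must satisfy 0 <= start < end <= seq length")
  }
  # per allele: sorted, non-overlapping
  ord <- order(features$allele, features$start)
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  by_a <- split(features, features$allele)
  for (fa in by_a) {
    if (nrow(fa) > 1L && any(fa$start[-1L] < fa$end[-nrow(fa)])) {
      stop("overlapping features on allele ", fa$allele[1])
    }
  }
  if (length(source) == 1L && is.null(names(source))) {
    source <- stats::setNames(rep(source, length(seq)), names(seq))
  }
  if (!all(names(seq) %in% names(source))) {
    stop("source must cover every allele")
  }
  source <- source[names(seq)]
  if (!all(source %in% c("base", "population"))) {
    stop("source must be 'base' or 'population'")
  }
  if (length(aliases) && !all(aliases %in% names(seq))) {
    stop("alias targets absent from the panel")
  }
  structure(list(seq = seq, features = features, source = source,
                 aliases = aliases),
            class = "hla_panel")
}

#' @export
print.hla_panel <- function(x, ...) {
  genes <- hla_gene(names(x$seq))
  cat(sprintf("HLA reference panel: %d alleles, %d gene(s) [%s]\n",
              length(x$seq), length(unique(genes)),
              paste(sort(unique(genes)), collapse = ", ")))
  cat(sprintf("  full-length (with introns): %d; population-sourced: %d; aliases: %d\n",
              sum(vapply(names(x$seq), function(a)
                any(x$features$allele == a & x$features$kind == "intron"),
                logical(1))),
              sum(x$source == "population"), length(x$aliases)))
  invisible(x)
}

#' Allele names and lengths of a panel
#' @param panel An `hla_panel`.
#' @return `panel_alleles`: character vector of allele names;
#'   `allele_lengths`: named integer vector of sequence lengths;
#'   `panel_genes`: sorted unique locus symbols.
#' @export
panel_alleles <- function(panel) names(panel$seq)

#' @rdname panel_alleles
#' @export
allele_lengths <- function(panel) {
  stats::setNames(nchar(panel$seq), names(panel$seq))
}

#' @rdname panel_alleles
#' @export
panel_genes <- function(panel) sort(unique(hla_gene(names(panel$seq))))

#' Read and write panels
#'
#' Panel FASTA headers are `>NAME optional-description` where NAME parses as
#' an allele name.  Features travel in a sidecar TSV with columns `allele`,
#' `kind`, `ordinal`, `start`, `end` (0-based half-open).  Aliases recorded
#' by [merge_panels()] are written as a two-column TSV (`alias`, `canonical`).
#'
#' @param fasta Path to the panel FASTA.
#' @param features_tsv Path to the feature sidecar TSV (optional on read).
#' @param source Source tag applied to all alleles read.
#' @return `read_panel()` returns an `hla_panel`; the writers return their
#'   first argument invisibly.
#' @export
read_panel <- function(fasta, features_tsv = NULL, source = "base") {
  ss <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(as.character(ss), nm)
  feats <- NULL
  if (!is.null(features_tsv)) {
    feats <- utils::read.delim(features_tsv, stringsAsFactors = FALSE)
  }
  hla_panel(seqs, feats, source = source)
}

#' @rdname read_panel
#' @param panel An `hla_panel` to write.
#' @param alias_tsv Optional path for the alias table.
#' @export
write_panel <- function(panel, fasta, features_tsv = NULL, alias_tsv = NULL) {
  ss <- Biostrings::DNAStringSet(panel$seq)
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(features_tsv)) {
    utils::write.table(panel$features, features_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(alias_tsv)) {
    utils::write.table(
      data.frame(alias = names(panel$aliases),
                 canonical = unname(panel$aliases)),
      alias_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(panel)
}

#' Augment a base panel with a population-specific panel
#'
#' Takes the union of the two panels' alleles.  When a population allele's
#' sequence is byte-identical to a base allele of the same gene, a single
#' entry is kept under the base (canonical) name and the population name is
#' recorded in `aliases`; the population panel typically extends known
#' alleles to full length, so genuinely novel sequences are appended with
#' `source = "population"`.
#'
#' @param base,population `hla_panel` objects.
#' @return The merged `hla_panel`.
#' @examples
#' base <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 4, seed = 1))
#' pop <- hla_panel(c("A*05:01" = base$seq[["A*01:01"]]),
#'                  source = "population")
#' merged <- merge_panels(base, pop)  # duplicate sequence: recorded as alias
#' merged$aliases
#' @export
merge_panels <- function(base, population) {
  stopifnot(inherits(base, "hla_panel"), inherits(population, "hla_panel"))
  seqs <- base$seq
  feats <- base$features
  source <- base$source
  aliases <- c(base$aliases, population$aliases)
  base_gene <- hla_gene(names(base$seq))
  for (nm in names(population$seq)) {
    pseq <- population$seq[[nm]]
    if (nm %in% names(seqs)) {
      if (!identical(unname(seqs[[nm]]), unname(pseq))) {
        stop(sprintf(
          "panel conflict: allele '%s' present in both panels with different sequences (%d vs %d bp)",
          nm, nchar(seqs[[nm]]), nchar(pseq)))
      }
      next  # same name, same sequence: keep the base entry
    }
    g <- hla_gene(nm)
    same_gene <- names(base$seq)[base_gene == g]
    hit <- same_gene[vapply(same_gene, function(b)
      identical(unname(base$seq[[b]]), unname(pseq)), logical(1))]
    if (length(hit)) {
      aliases[nm] <- hit[1]  # base name stays canonical
    } else {
      seqs[nm] <- pseq
      source[nm] <- "population"
      pf <- population$features[population$features$allele == nm, ,
                                drop = FALSE]
      feats <- rbind(feats, pf)
    }
  }
  hla_panel(seqs, feats, source = source, aliases = aliases)
}

#' Extract concatenated feature subsequences of one allele
#'
#' @param panel An `hla_panel`.
#' @param allele Allele name present in the panel.
#' @param features `data.frame` with columns `kind` and `ordinal` giving the
#'   features to extract, in order; defaults to exons 2 and 3, the
#'   peptide-binding-domain exons of class-I genes.
#' @return A single nucleotide string, the concatenation of the requested
#'   subsequences (empty string for an empty request).
#' @export
feature_subsequence <- function(panel, allele, features = exon23()) {
  if (!allele %in% names(panel$seq)) {
    stop(sprintf("allele '%s' not in panel", allele))
  }
  if (nrow(features) == 0L) return("")
  fa <- panel$features[panel$features$allele == allele, , drop = FALSE]
  out <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    hit <- fa[fa$kind == features$kind[i] & fa$ordinal == features$ordinal[i],
              , drop = FALSE]
    if (nrow(hit) != 1L) {
      stop(sprintf("allele '%s' has no %s %d annotation",
                   allele, features$kind[i], features$ordinal[i]))
    }
    # 0-based half-open -> substr's 1-based inclusive
    out[i] <- substr(panel$seq[[allele]], hit$start + 1L, hit$end)
  }
  paste(out, collapse = "")
}

#' @rdname feature_subsequence
#' @export
exon23 <- function() data.frame(kind = "exon", ordinal = 2:3)

#' Group a gene's alleles by feature-subsequence identity
#'
#' Partitions the alleles of one gene so that two alleles share a group if
#' and only if their concatenated subsequences over the requested features
#' are identical.  Over exons 2 and 3 this reproduces G-group-style
#' ambiguity: alleles in one group cannot be distinguished by any method
#' that reads only those exons (the C*04:01 / C*04:82 situation).
#'
#' @inheritParams feature_subsequence
#' @param gene Locus symbol.
#' @return Object of class `hla_groups`: a list with `gene`, `feature_key`
#'   (the feature request) and `members`, a list of character vectors (each
#'   sorted), ordered by the smallest member name of each group.
#' @export
feature_identity_groups <- function(panel, gene, features = exon23()) {
  alleles <- names(panel$seq)[hla_gene(names(panel$seq)) == gene]
  if (!length(alleles)) stop(sprintf("no alleles of gene '%s' in panel", gene))
  keys <- vapply(alleles, feature_subsequence, character(1),
                 panel = panel, features = features)
  grp <- split(alleles, keys)
  members <- lapply(unname(grp), sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  structure(list(gene = gene, feature_key = features, members = members),
            class = "hla_groups")
}

#' @export
print.hla_groups <- function(x, ...) {
  cat(sprintf("%d feature-identity group(s) for gene %s (%s)\n",
              length(x$members), x$gene,
              paste(paste0(x$feature_key$kind, x$feature_key$ordinal),
                    collapse = "+")))
  multi <- Filter(function(m) length(m) > 1L, x$members)
  for (m in multi) cat("  ambiguous: ", paste(m, collapse = " = "), "\n")
  invisible(x)
}

#' Reduce a panel to exon-only sequences
#'
#' Replaces every allele's sequence by the concatenation of its exons (in
#' ordinal order) with recomputed exon coordinates, discarding introns and
#' UTRs.  This mimics an exon-only reference set; alleles differing only in
#' introns collapse to identical sequences under it, which is exactly the
#' ambiguity a full-length panel removes.
#'
#' @param panel An `hla_panel` whose alleles all carry exon annotations.
#' @return An `hla_panel` of exon-only sequences.
#' @export
exon_only_panel <- function(panel) {
  seqs <- character(0)
  feats <- NULL
  for (nm in names(panel$seq)) {
    fa <- panel$features[panel$features$allele == nm &
                           panel$features$kind == "exon", , drop = FALSE]
    fa <- fa[order(fa$ordinal), , drop = FALSE]
    if (!nrow(fa)) stop(sprintf("allele '%s' has no exon annotations", nm))
    parts <- substring(panel$seq[[nm]], fa$start + 1L, fa$end)
    seqs[nm] <- paste(parts, collapse = "")
    ends <- cumsum(nchar(parts))
    feats <- rbind(feats, data.frame(
      allele = nm, kind = "exon", ordinal = fa$ordinal,
      start = c(0L, ends[-length(ends)]), end = ends))
  }
  hla_panel(seqs, feats, source = panel$source, aliases = panel$aliases)
}
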