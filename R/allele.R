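#' Parse an HLA allele name
#'
#' Parses names in standard HLA nomenclature, `GENE*F1:F2[:F3[:F4]]` with an
#' optional expression suffix (one of N, L, S, C, A, Q) and an optional
#' trailing `G` marking a G-group name (alleles identical across the
#' peptide-binding-domain exons).  Whitespace between the last field and the
#' suffix or G marker is tolerated, as typing reports often print the suffix
#' detached (e.g. `"A*02:15 N"`).
#'
#' @param text A single allele name, e.g. `"A*02:15N"` or `"A*01:01:01G"`.
#' @return An object of class `hla_allele`: a list with components `gene`
#'   (locus symbol), `fields` (character vector of 1-4 numeric field strings,
#'   leading zeros preserved), `suffix` (expression marker or `""`) and
#'   `g_group` (logical).
#' @examples
#' parse_hla("A*02:15N")
#' parse_hla("A*01:01:01 G")
#' @seealso [hla_truncate()] for reducing resolution, [format.hla_allele()].
#' @export
parse_hla <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("allele name must be a single non-empty string")
  }
  txt <- trimws(text)
  m <- regexec("^([A-Z][A-Z0-9]*)\\*(\\d+(?::\\d+)*)\\s*([NLSCAQ])?\\s*(G)?$",
               txt)
  parts <- regmatches(txt, m)[[1]]
  if (length(parts) == 0L) {
    # diagnose the offending token for a useful message
    if (!grepl("\\*", txt)) {
      stop(sprintf("malformed allele name '%s': missing '*' separator", txt))
    }
    bad <- strsplit(sub("^[^*]*\\*", "", txt), ":")[[1]]
    bad <- bad[!grepl("^\\d+$", sub("\\s*[NLSCAQG]?\\s*$", "", bad))]
    stop(sprintf("malformed allele name '%s': bad token '%s'",
                 txt, if (length(bad)) bad[1] else txt))
  }
  fields <- strsplit(parts[3], ":", fixed = TRUE)[[1]]
  if (length(fields) > 4L) {
    stop(sprintf("malformed allele name '%s': more than 4 fields", txt))
  }
  structure(list(gene = parts[2], fields = fields,
                 suffix = parts[4], g_group = nzchar(parts[5])),
            class = "hla_allele")
}

#' @method format hla_allele
#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$gene, "*", paste(x$fields, collapse = ":"), x$suffix,
         if (x$g_group) "G" else "")
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

#' Truncate allele names to a lower field resolution
#'
#' Keeps the first `n_fields` colon-separated fields of each name; the
#' expression suffix is retained (an `A*02:15N` stays null at any
#' resolution).  Names that already have `n_fields` or fewer fields are
#' returned unchanged.  Typing evaluation in this package is conventionally
#' done at 2-field resolution, the level that determines the protein
#' sequence.
#'
#' @param x Character vector of allele names (or a single `hla_allele`).
#' @param n_fields Number of fields to keep, between 1 and 4.
#' @return Character vector of truncated names (or an `hla_allele` when the
#'   input was one).
#' @examples
#' hla_truncate(c("A*26:03:01", "A*02:15N"), 2)
#' @export
hla_truncate <- function(x, n_fields = 2L) {
  stopifnot(length(n_fields) == 1L, n_fields >= 1L, n_fields <= 4L)
  if (inherits(x, "hla_allele")) {
    x$fields <- x$fields[seq_len(min(length(x$fields), n_fields))]
    return(x)
  }
  vapply(x, function(nm) {
    a <- parse_hla(nm)
    a$fields <- a$fields[seq_len(min(length(a$fields), n_fields))]
    format(a)
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the locus symbol from allele names
#'
#' @param x Character vector of allele names.
#' @return Character vector of gene (locus) symbols.
#' @examples
#' hla_gene(c("A*02:01", "B*15:428"))
#' @export
hla_gene <- function(x) {
  vapply(x, function(nm) parse_hla(nm)$gene, character(1), USE.NAMES = FALSE)
}
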