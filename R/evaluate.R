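#' Count matching allele slots between a called and a true genotype
#'
#' Genotypes are unordered pairs, so the score is the maximum number of
#' matched slots over the two possible pairings of called against true
#' alleles.  A `"fail"` slot never matches.
#'
#' @param called,truth Character vectors of length 2 (allele names at a
#'   common resolution; `called` slots may be `"fail"`).
#' @param check_gene When `TRUE`, error if the two pairs are from different
#'   loci.
#' @return Integer in `0:2`.
#' @examples
#' match_genotype(c("A*02:01", "A*24:02"), c("A*24:02", "A*02:01"))  # 2
#' match_genotype(c("fail", "fail"), c("A*01:01", "A*02:01"))        # 0
#' @export
match_genotype <- function(called, truth, check_gene = TRUE) {
  stopifnot(length(called) == 2L, length(truth) == 2L)
  if (check_gene) {
    gs <- unique(c(hla_gene(truth), hla_gene(called[called != "fail"])))
    if (length(gs) > 1L) {
      stop("gene mismatch between called and true genotypes: ",
           paste(gs, collapse = " vs "))
    }
  }
  slot_eq <- function(a, b) a != "fail" && a == b
  p1 <- slot_eq(called[1], truth[1]) + slot_eq(called[2], truth[2])
  p2 <- slot_eq(called[1], truth[2]) + slot_eq(called[2], truth[1])
  as.integer(max(p1, p2))
}

round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

truncate_typing <- function(x, resolution) {
  sel <- x != "fail"
  x[sel] <- hla_truncate(x[sel], resolution)
  x
}

join_calls_truth <- function(calls, truth) {
  key_t <- paste(truth$sample, truth$gene)
  key_c <- paste(calls$sample, calls$gene)
  if (anyDuplicated(key_c)) {
    stop("duplicate calls for sample/gene: ",
         paste(unique(key_c[duplicated(key_c)]), collapse = ", "))
  }
  if (anyDuplicated(key_t)) {
    stop("duplicate truth records for sample/gene: ",
         paste(unique(key_t[duplicated(key_t)]), collapse = ", "))
  }
  m <- match(key_t, key_c)
  list(m = m)
}

call_slots_of <- function(calls, idx) {
  if (is.na(idx)) return(c("fail", "fail"))
  row <- calls[idx, ]
  if (!is.null(row$status) && !is.na(row$status) && row$status == "fail") {
    return(c("fail", "fail"))
  }
  c(row$allele1, row$allele2)
}

#' Allele-level prediction accuracy per gene
#'
#' The evaluation metric is allele-level: each truth record contributes two
#' allele slots, a called genotype earns [match_genotype()] of them, and the
#' per-gene accuracy is `100 * n_correct / n` rounded half-up to one
#' decimal.  A truth record with no call (or a failed call) contributes two
#' incorrect slots... except that calls may also carry a single `"fail"`
#' slot, which then counts as exactly one incorrect allele.
#'
#' @param calls `data.frame` with columns `sample`, `gene`, `allele1`,
#'   `allele2` (slots may be `"fail"`) and optionally `status`.
#' @param truth `data.frame` with columns `sample`, `gene`, `allele1`,
#'   `allele2`.
#' @param resolution Field resolution at which both sides are compared.
#' @return `data.frame` with one row per gene: `gene`, `n`, `n_correct`,
#'   `accuracy_pct`.
#' @export
accuracy_table <- function(calls, truth, resolution = 2L) {
  j <- join_calls_truth(calls, truth)
  genes <- sort(unique(truth$gene))
  out <- lapply(genes, function(g) {
    sel <- which(truth$gene == g)
    n_correct <- 0L
    for (k in sel) {
      tt <- truncate_typing(c(truth$allele1[k], truth$allele2[k]), resolution)
      cc <- truncate_typing(call_slots_of(calls, j$m[k]), resolution)
      n_correct <- n_correct + match_genotype(cc, tt, check_gene = FALSE)
    }
    n <- 2L * length(sel)
    data.frame(gene = g, n = n, n_correct = n_correct,
               accuracy_pct = round_half_up(100 * n_correct / n, 1L))
  })
  do.call(rbind, out)
}

# best pairing of call slots onto truth slots; identity pairing on ties
pair_slots <- function(cc, tt) {
  eq <- function(a, b) a != "fail" & a == b
  p1 <- eq(cc[1], tt[1]) + eq(cc[2], tt[2])
  p2 <- eq(cc[1], tt[2]) + eq(cc[2], tt[1])
  if (p2 > p1) cc[c(2, 1)] else cc
}

#' Listing of calls discordant with the truth
#'
#' One record per (gene, true type, called type) combination with the number
#' of discordant allele slots, mirroring the structure of published
#' discordance tables.  The truth count `true_n` accumulates over all allele
#' slots of that true type in the dataset, discordant or not.
#'
#' @inheritParams accuracy_table
#' @return `data.frame` with columns `gene`, `true_type`, `true_n`,
#'   `called_type` (possibly `"fail"`), `count`, sorted by gene, true type,
#'   called type; zero rows when every call is correct.
#' @export
discordance_table <- function(calls, truth, resolution = 2L) {
  j <- join_calls_truth(calls, truth)
  recs <- list()
  truth_slots <- data.frame(
    gene = rep(truth$gene, 2L),
    type = truncate_typing(c(truth$allele1, truth$allele2), resolution))
  for (k in seq_len(nrow(truth))) {
    tt <- truncate_typing(c(truth$allele1[k], truth$allele2[k]), resolution)
    cc <- truncate_typing(call_slots_of(calls, j$m[k]), resolution)
    cc <- pair_slots(cc, tt)
    for (s in 1:2) {
      if (cc[s] == "fail" || cc[s] != tt[s]) {
        recs[[length(recs) + 1L]] <- data.frame(
          gene = truth$gene[k], true_type = tt[s], called_type = cc[s])
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(gene = character(0), true_type = character(0),
                      true_n = integer(0), called_type = character(0),
                      count = integer(0)))
  }
  recs <- do.call(rbind, recs)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(recs))),
    by = recs[, c("gene", "true_type", "called_type")], FUN = sum)
  n_of <- stats::aggregate(
    list(true_n = rep(1L, nrow(truth_slots))),
    by = truth_slots[, c("gene", "type")], FUN = sum)
  agg$true_n <- n_of$true_n[match(paste(agg$gene, agg$true_type),
                                  paste(n_of$gene, n_of$type))]
  agg <- agg[order(agg$gene, agg$true_type, agg$called_type), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("gene", "true_type", "true_n", "called_type", "count")]
}

group_id_of <- function(groups, allele) {
  for (gi in seq_along(groups$members)) {
    if (allele %in% groups$members[[gi]]) return(gi)
  }
  NA_integer_
}

resolve_groups <- function(groups, gene) {
  if (inherits(groups, "hla_groups")) {
    if (groups$gene != gene) return(NULL)
    return(groups)
  }
  for (g in groups) if (g$gene == gene) return(g)
  NULL
}

#' Report conflicts between two typing methods, with exon-2/3 context
#'
#' Compares two typing result sets (for example an exon-2/3 hybridisation
#' method against full-gene sequencing) sample by sample and gene by gene.
#' For each conflicting allele slot the report states whether the two
#' conflicting alleles lie in one exon-2/3 identity group — in which case
#' the methods could never have agreed from exons 2 and 3 alone — and which
#' allele this package's own caller picked for that slot.
#'
#' @param typings_a,typings_b Typing `data.frame`s (`sample`, `gene`,
#'   `allele1`, `allele2`); `typings_a` is the reference side reported as
#'   `type_a`.
#' @param calls Optional calls `data.frame` in the same layout (this
#'   package's results); may be `NULL`.
#' @param groups An `hla_groups` object or a list of them (one per gene),
#'   computed over exons 2 and 3 of the same panel.
#' @param resolution Comparison resolution.
#' @return `data.frame` with columns `sample`, `gene`, `type_a`, `type_b`,
#'   `same_exon23_group` (logical; `NA` when either allele is absent from
#'   the grouping universe) and `resolving_call` (`NA` without calls).
#' @export
ambiguity_report <- function(typings_a, typings_b, calls = NULL, groups,
                             resolution = 2L) {
  key_a <- paste(typings_a$sample, typings_a$gene)
  key_b <- paste(typings_b$sample, typings_b$gene)
  common <- intersect(key_a, key_b)
  rows <- list()
  for (kk in common) {
    ia <- match(kk, key_a); ib <- match(kk, key_b)
    aa <- truncate_typing(c(typings_a$allele1[ia], typings_a$allele2[ia]),
                          resolution)
    bb <- truncate_typing(c(typings_b$allele1[ib], typings_b$allele2[ib]),
                          resolution)
    bb <- pair_slots(bb, aa)
    for (s in 1:2) {
      if (aa[s] == bb[s]) next
      gene <- typings_a$gene[ia]
      gg <- resolve_groups(groups, gene)
      same <- NA
      if (!is.null(gg) && aa[s] != "fail" && bb[s] != "fail") {
        ga <- group_id_of(gg, aa[s])
        gb <- group_id_of(gg, bb[s])
        same <- if (is.na(ga) || is.na(gb)) NA else ga == gb
      }
      resolving <- NA_character_
      if (!is.null(calls)) {
        ic <- match(kk, paste(calls$sample, calls$gene))
        if (!is.na(ic)) {
          cc <- truncate_typing(call_slots_of(calls, ic), resolution)
          cc <- pair_slots(cc, aa)
          resolving <- cc[s]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = typings_a$sample[ia], gene = gene,
        type_a = aa[s], type_b = bb[s],
        same_exon23_group = same, resolving_call = resolving)
    }
  }
  if (!length(rows)) {
    return(data.frame(sample = character(0), gene = character(0),
                      type_a = character(0), type_b = character(0),
                      same_exon23_group = logical(0),
                      resolving_call = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sample, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Alleles indistinguishable from a genotype over exons 2 and 3
#'
#' Returns the union of the exon-2/3 identity groups of the given alleles —
#' every allele an exon-2/3-only method could report for this genotype.
#' The simulator uses this to emulate hybridisation-style typing.
#'
#' @param alleles Character vector of allele names (all in the grouping's
#'   universe).
#' @param groups An `hla_groups` object (or list of them) for the alleles'
#'   gene.
#' @return Sorted character vector of allele names.
#' @export
project_to_exon23 <- function(alleles, groups) {
  out <- character(0)
  for (a in alleles) {
    gg <- resolve_groups(groups, hla_gene(a))
    gi <- if (is.null(gg)) NA_integer_ else group_id_of(gg, a)
    if (is.na(gi)) stop(sprintf("allele '%s' absent from grouping", a))
    out <- c(out, gg$members[[gi]])
  }
  sort(unique(out))
}

#' Read / write typing tables (truth or calls) as TSV
#'
#' Columns `sample`, `gene`, `allele1`, `allele2` and, for calls, `status`.
#' @param path TSV path.
#' @export
read_typings <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_typings
#' @param typings A typing `data.frame`.
#' @export
write_typings <- function(typings, path) {
  utils::write.table(typings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(typings)
}
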