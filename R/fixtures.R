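#' Published discordance counts for the SJS validation dataset
#'
#' The shipped table lists, per gene and true 2-field type, how many allele
#' slots each tool version (`v1`: the original exon-centric reference set;
#' `v2`: the panel augmented with full-length population alleles) called
#' discordantly, together with the truth count of each type.  `"fail"` as a
#' called type marks a slot the tool could not call.  The dataset evaluated
#' 228 alleles (114 individuals) per gene.
#'
#' @return `data.frame` with columns `gene`, `true_type`, `true_n`,
#'   `method`, `called_type`, `count`.
#' @seealso [build_discordance_dataset()] to expand the counts into
#'   slot-level truth and call records.
#' @export
sjs_discordances <- function() {
  utils::read.delim(system.file("extdata", "sjs_discordances.tsv",
                                package = "hlacall"),
                    stringsAsFactors = FALSE)
}

#' Expand a discordance count table into truth and call records
#'
#' Reconstructs a slot-level dataset consistent with a published discordance
#' summary: per gene, truth allele slots are laid out according to the
#' `true_n` counts (padded to `n_per_gene` slots with a correct filler type)
#' and paired into synthetic samples; each method's calls start as a copy of
#' the truth and the listed discordances are then injected slot by slot.
#' Running [accuracy_table()] and [discordance_table()] on the result
#' recomputes the published accuracies and reproduces the input table.
#'
#' @param disc Count table in the layout of [sjs_discordances()].
#' @param n_per_gene Total allele slots per gene (default 228).
#' @return List with `truth` (typing `data.frame`) and `calls`, a named
#'   list of call `data.frame`s, one per method in `disc`.
#' @examples
#' ds <- build_discordance_dataset(sjs_discordances())
#' accuracy_table(ds$calls$v2, ds$truth)
#' @export
build_discordance_dataset <- function(disc, n_per_gene = 228L) {
  stopifnot(n_per_gene %% 2L == 0L)
  methods <- sort(unique(disc$method))
  truth_rows <- list()
  call_rows <- stats::setNames(vector("list", length(methods)), methods)
  for (g in sort(unique(disc$gene))) {
    dg <- disc[disc$gene == g, , drop = FALSE]
    types <- unique(dg[, c("true_type", "true_n")])
    if (sum(types$true_n) > n_per_gene) {
      stop("true_n counts exceed n_per_gene for gene ", g)
    }
    filler <- paste0(g, "*90:01")
    if (filler %in% types$true_type) stop("filler name collides")
    slots <- c(rep(types$true_type, types$true_n),
               rep(filler, n_per_gene - sum(types$true_n)))
    n_samples <- n_per_gene %/% 2L
    sample_ids <- sprintf("SJS%s%03d", g, seq_len(n_samples))
    truth_rows[[g]] <- data.frame(
      sample = sample_ids, gene = g,
      allele1 = slots[2L * seq_len(n_samples) - 1L],
      allele2 = slots[2L * seq_len(n_samples)])
    for (m in methods) {
      dm <- dg[dg$method == m, , drop = FALSE]
      call_slots <- slots
      open <- rep(TRUE, length(slots))
      for (r in seq_len(nrow(dm))) {
        idx <- which(slots == dm$true_type[r] & open)
        if (length(idx) < dm$count[r]) {
          stop("not enough truth slots of ", dm$true_type[r],
               " to place discordances")
        }
        idx <- idx[seq_len(dm$count[r])]
        call_slots[idx] <- dm$called_type[r]
        open[idx] <- FALSE
      }
      call_rows[[m]][[g]] <- data.frame(
        sample = sample_ids, gene = g,
        allele1 = call_slots[2L * seq_len(n_samples) - 1L],
        allele2 = call_slots[2L * seq_len(n_samples)])
    }
  }
  list(truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
       calls = lapply(call_rows, function(x)
         do.call(rbind, c(x, list(make.row.names = FALSE)))))
}
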