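#' Diploid genotype call for one gene from per-allele depths
#'
#' Alleles are first collapsed to the reporting resolution (depths summed
#' within a collapsed name, so 3rd/4th-field variants pool their support),
#' then ranked by depth with ties broken by the lexicographically smallest
#' name.  With `d1 >= d2` the top two collapsed depths and `g` the sample's
#' genome-wide mean depth, the three-way rule is:
#' \itemize{
#'   \item `d1 < delta * g / 2`: \strong{fail} — not even one allele carries
#'     the minimum support expected of a single haplotype;
#'   \item else if `d2 >= tau * d1` and `d2 >= delta * g / 2`:
#'     \strong{heterozygous}, the top two alleles;
#'   \item else: \strong{homozygous} for the top allele.
#' }
#' At whole-genome depth each of two heterozygous alleles should carry about
#' half the gene's coverage, hence the `g / 2` scaling.
#'
#' @param depths Named numeric vector of depths for the alleles of one gene.
#' @param genome_mean_depth Sample mean autosomal depth (> 0); supplied by
#'   the user or the simulator truth, never estimated here.
#' @param tau Heterozygosity ratio threshold in (0, 1]: minimum `d2 / d1`.
#' @param delta Minimum-depth fraction (> 0) of `genome_mean_depth / 2`.
#' @param resolution Reporting resolution in fields (default 2).
#' @param gene Optional gene label recorded in the call (inferred from the
#'   allele names when omitted).
#' @param sample Optional sample label.
#' @return A one-row `data.frame` (class `hla_call`): `sample`, `gene`,
#'   `status` (`"called"`/`"fail"`), `allele1`, `allele2`, `depth1`,
#'   `depth2`.  Equal allele names mean a homozygous call; on failure the
#'   allele slots hold `"fail"`.
#' @export
call_gene <- function(depths, genome_mean_depth, tau = 0.4, delta = 0.3,
                      resolution = 2L, gene = NULL, sample = NA_character_) {
  if (!length(depths)) stop("empty depth table")
  stopifnot(genome_mean_depth > 0, tau > 0, tau <= 1, delta > 0)
  if (is.null(gene)) gene <- unique(hla_gene(names(depths)))
  if (length(gene) != 1L) stop("depths must cover a single gene")
  short <- hla_truncate(names(depths), resolution)
  d <- tapply(depths, short, sum)
  d <- d[order(-d, names(d))]
  d1 <- unname(d[1])
  d2 <- if (length(d) >= 2L) unname(d[2]) else 0
  min_hap <- delta * genome_mean_depth / 2
  if (d1 < min_hap) {
    out <- data.frame(sample = sample, gene = gene, status = "fail",
                      allele1 = "fail", allele2 = "fail",
                      depth1 = d1, depth2 = d2)
  } else if (d2 >= tau * d1 && d2 >= min_hap) {
    out <- data.frame(sample = sample, gene = gene, status = "called",
                      allele1 = names(d)[1], allele2 = names(d)[2],
                      depth1 = d1, depth2 = d2)
  } else {
    out <- data.frame(sample = sample, gene = gene, status = "called",
                      allele1 = names(d)[1], allele2 = names(d)[1],
                      depth1 = d1, depth2 = d1)
  }
  class(out) <- c("hla_call", "data.frame")
  out
}

#' Call genotypes for every gene of a panel from a fitted mixture
#'
#' Splits the fitted per-allele depths by gene and applies [call_gene()]
#' once per gene present in the panel; genes without aligned reads fail.
#'
#' @param fit An `hla_mixture` fitted with `allele_lengths` (so depths are
#'   available), or a named numeric vector of per-allele depths covering the
#'   panel.
#' @param panel The `hla_panel` the mixture was fitted against.
#' @inheritParams call_gene
#' @return `data.frame` (class `hla_call`) with one row per gene, ordered by
#'   gene.
#' @examples
#' sim <- simulate_dataset(n_samples = 1, seed = 1)
#' ev <- align_reads(sim$reads[[1]], sim$panel)
#' fit <- hla_mixture(ev, allele_lengths = allele_lengths(sim$panel))
#' call_genotypes(fit, sim$panel, genome_mean_depth = 30)
#' @export
call_genotypes <- function(fit, panel, genome_mean_depth, tau = 0.4,
                           delta = 0.3, resolution = 2L,
                           sample = NA_character_) {
  depths <- if (inherits(fit, "hla_mixture")) {
    if (is.null(fit$depth)) {
      stop("mixture was fitted without allele_lengths; no depths available")
    }
    fit$depth
  } else {
    fit
  }
  if (!all(names(panel$seq) %in% names(depths))) {
    stop("depths must cover every panel allele")
  }
  genes <- panel_genes(panel)
  gene_of <- hla_gene(names(depths))
  calls <- lapply(genes, function(g) {
    call_gene(depths[gene_of == g], genome_mean_depth, tau = tau,
              delta = delta, resolution = resolution, gene = g,
              sample = sample)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("hla_call", "data.frame")
  out
}

#' @export
print.hla_call <- function(x, ...) {
  cat("diploid genotype call(s):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
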