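#' Type one sample end to end
#'
#' Convenience wrapper chaining the pipeline for a single sample: align the
#' reads against the panel ([align_reads()]), fit the read mixture
#' ([hla_mixture()]), convert expected per-allele depths into diploid calls
#' ([call_genotypes()]).
#'
#' @param reads Named character vector or `data.frame` (`id`, `seq`) of the
#'   sample's reads.
#' @param panel An `hla_panel`.
#' @param genome_mean_depth Sample mean autosomal depth.
#' @param sample Sample label carried into the calls.
#' @param eps,max_mismatches,k,paired Passed to [align_reads()].
#' @param alpha0,tol,max_iter Passed to [hla_mixture()].
#' @param tau,delta,resolution Passed to [call_genotypes()].
#' @return An `hla_call` `data.frame`, one row per panel gene; the fitted
#'   `hla_mixture` is attached as attribute `"fit"`.
#' @examples
#' sim <- simulate_dataset(n_samples = 1, seed = 4)
#' hla_type(sim$reads[[1]], sim$panel, genome_mean_depth = sim$coverage,
#'          sample = names(sim$reads)[1])
#' @export
hla_type <- function(reads, panel, genome_mean_depth,
                     sample = NA_character_, eps = 0.01,
                     max_mismatches = 6L, k = 21L, paired = FALSE,
                     alpha0 = 0.2, tol = 1e-6, max_iter = 1000L,
                     tau = 0.4, delta = 0.3, resolution = 2L) {
  ev <- align_reads(reads, panel, eps = eps,
                    max_mismatches = max_mismatches, k = k, paired = paired)
  fit <- hla_mixture(ev, method = "vb", alpha0 = alpha0, tol = tol,
                     max_iter = max_iter,
                     allele_lengths = allele_lengths(panel))
  calls <- call_genotypes(fit, panel, genome_mean_depth, tau = tau,
                          delta = delta, resolution = resolution,
                          sample = sample)
  attr(calls, "fit") <- fit
  calls
}

#' Run a simulated typing study through the full pipeline
#'
#' Types every sample of a [simulate_dataset()] result (optionally against
#' a different panel, e.g. an [exon_only_panel()]) and evaluates the calls
#' against the simulated truth.
#'
#' @param sim A [simulate_dataset()] result.
#' @param panel Panel to type against; defaults to the simulation's own.
#' @param resolution Reporting/evaluation resolution.
#' @param ... Further arguments passed to [hla_type()].
#' @return List with `calls` (all samples), `accuracy`
#'   ([accuracy_table()]), `discordance` ([discordance_table()]) and
#'   `truth`.
#' @export
run_typing_experiment <- function(sim, panel = sim$panel, resolution = 2L,
                                  ...) {
  calls <- lapply(names(sim$reads), function(smp) {
    hla_type(sim$reads[[smp]], panel,
             genome_mean_depth = sim$coverage, sample = smp,
             resolution = resolution, ...)
  })
  calls <- do.call(rbind, lapply(calls, function(x) {
    attr(x, "fit") <- NULL
    as.data.frame(x)
  }))
  list(calls = calls,
       accuracy = accuracy_table(calls, sim$truth, resolution = resolution),
       discordance = discordance_table(calls, sim$truth,
                                       resolution = resolution),
       truth = sim$truth)
}

#' Materialise a simulated study as files
#'
#' Writes everything the command-line interface consumes: the panel FASTA
#' with its feature sidecar, one FASTQ per sample, and the truth TSV.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(sim$panel, file.path(dir, "panel.fa"),
              features_tsv = file.path(dir, "features.tsv"))
  write_typings(sim$truth, file.path(dir, "truth.tsv"))
  for (smp in names(sim$reads)) {
    write_fastq(sim$reads[[smp]], file.path(dir, paste0(smp, ".fastq")))
  }
  invisible(dir)
}
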