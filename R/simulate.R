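with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

mutate_seq <- function(x, rate) {
  idx <- which(stats::runif(length(x)) < rate)
  if (length(idx)) {
    cur <- match(x[idx], BASES) - 1L
    x[idx] <- BASES[((cur + sample.int(3L, length(idx), replace = TRUE)) %%
                       4L) + 1L]
  }
  x
}

#' Specification of a synthetic reference panel
#'
#' The default layout emulates a class-I HLA gene: 8 exons embedded in a
#' ~3 kb genomic sequence, flanked and separated by UTRs/introns; the exon
#' lengths approximate a class-I transcript with the large exons 2-4
#' encoding the extracellular domains.  Alleles of one gene are generated
#' by mutating a shared ancestral sequence so that two alleles differ at a
#' rate close to `inter_allele_divergence` per site.  `n_exon23_twins`
#' allele pairs per gene are engineered to be identical over all exons
#' (hence over exons 2+3, the peptide-binding-domain exons) while differing
#' in introns — the situation in which only a full-length panel can
#' separate the pair.
#'
#' @param n_genes,alleles_per_gene,gene_length Positive counts.
#' @param exon_lengths Integer vector of per-exon lengths.
#' @param inter_allele_divergence Pairwise substitution rate between
#'   alleles, in (0, 0.1].
#' @param n_exon23_twins Engineered twin pairs per gene, at most
#'   `alleles_per_gene / 2`.
#' @param seed Seed for the panel's single pseudo-random stream.
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(n_genes = 3L, alleles_per_gene = 20L,
                       gene_length = 3000L,
                       exon_lengths = c(73L, 270L, 276L, 276L, 117L, 33L,
                                        48L, 5L),
                       inter_allele_divergence = 0.02,
                       n_exon23_twins = 1L, seed = 1L) {
  stopifnot(n_genes >= 1L, alleles_per_gene >= 1L, gene_length >= 1L,
            all(exon_lengths >= 1L), length(exon_lengths) >= 3L,
            inter_allele_divergence > 0, inter_allele_divergence <= 0.1,
            n_exon23_twins >= 0L,
            n_exon23_twins <= alleles_per_gene / 2)
  gaps <- length(exon_lengths) + 1L
  slack <- gene_length - sum(exon_lengths)
  if (slack < gaps) {
    stop("gene_length leaves no room for introns/UTRs")
  }
  if (n_exon23_twins > 0L && slack == 0L) {
    stop("twin pairs require nonzero intron length")
  }
  structure(list(n_genes = as.integer(n_genes),
                 alleles_per_gene = as.integer(alleles_per_gene),
                 gene_length = as.integer(gene_length),
                 exon_lengths = as.integer(exon_lengths),
                 inter_allele_divergence = inter_allele_divergence,
                 n_exon23_twins = as.integer(n_exon23_twins),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

spec_layout <- function(spec) {
  ne <- length(spec$exon_lengths)
  gap <- (spec$gene_length - sum(spec$exon_lengths)) %/% (ne + 1L)
  rest <- (spec$gene_length - sum(spec$exon_lengths)) %% (ne + 1L)
  kinds <- character(0); ordinals <- integer(0); lens <- integer(0)
  add <- function(k, o, l) {
    kinds <<- c(kinds, k); ordinals <<- c(ordinals, o); lens <<- c(lens, l)
  }
  add("UTR", 1L, gap)
  for (e in seq_len(ne)) {
    add("exon", e, spec$exon_lengths[e])
    if (e < ne) add("intron", e, gap)
  }
  add("UTR", 2L, gap + rest)
  ends <- cumsum(lens)
  data.frame(kind = kinds, ordinal = ordinals,
             start = c(0L, ends[-length(ends)]), end = ends)
}

#' Generate a synthetic reference panel
#'
#' Deterministic given `spec$seed`; all sampling draws from a single stream
#' in a fixed order (genes, then alleles within a gene, then twin
#' overwrites).  The engineered twin structure is verified post hoc with
#' [feature_identity_groups()]: exactly `n_exon23_twins` exon-2/3 identity
#' groups of size 2 per gene, everything else singleton, and the members of
#' each twin pair differing outside their exons.
#'
#' @param spec A [panel_spec()].
#' @return An `hla_panel`.
#' @export
make_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  layout <- spec_layout(spec)
  genes <- LETTERS[seq_len(spec$n_genes)]
  with_seed(spec$seed, {
    seqs <- character(0)
    feats <- NULL
    ex <- layout[layout$kind == "exon", , drop = FALSE]
    ex23_sites <- unlist(lapply(which(ex$ordinal %in% 2:3), function(e)
      (ex$start[e] + 1L):ex$end[e]))
    for (g in genes) {
      anc <- sample(BASES, spec$gene_length, replace = TRUE)
      al <- vector("list", spec$alleles_per_gene)
      for (a in seq_len(spec$alleles_per_gene)) {
        al[[a]] <- mutate_seq(anc, spec$inter_allele_divergence / 2)
      }
      # resolve accidental exon-2/3 collisions (rare at these divergences)
      # by re-drawing the colliding allele's exon-2/3 sites from the
      # ancestor; keeps the stream deterministic
      for (attempt in 1:50) {
        keys <- vapply(al, function(x)
          paste(x[ex23_sites], collapse = ""), character(1))
        dup <- which(duplicated(keys))
        if (!length(dup)) break
        for (a in dup) {
          al[[a]][ex23_sites] <-
            mutate_seq(anc[ex23_sites], spec$inter_allele_divergence / 2)
        }
      }
      for (t in seq_len(spec$n_exon23_twins)) {
        p <- 2L * t - 1L; q <- 2L * t
        for (e in seq_len(nrow(ex))) {
          rng <- (ex$start[e] + 1L):ex$end[e]
          al[[q]][rng] <- al[[p]][rng]
        }
        if (identical(al[[p]], al[[q]])) {
          stop("twin pair identical everywhere; no intronic difference left")
        }
      }
      for (a in seq_len(spec$alleles_per_gene)) {
        nm <- sprintf("%s*%02d:01", g, a)
        seqs[nm] <- paste(al[[a]], collapse = "")
        feats <- rbind(feats, cbind(allele = nm, layout))
      }
    }
    panel <- hla_panel(seqs, feats, source = "base")
    for (g in genes) {
      sizes <- lengths(feature_identity_groups(panel, g)$members)
      if (sum(sizes > 1L) != spec$n_exon23_twins || any(sizes > 2L)) {
        stop("accidental exon-2/3 identity collision; use another seed")
      }
    }
    panel
  })
}

#' Twin-pair allele names of a simulated panel
#'
#' @param spec The [panel_spec()] the panel was built from.
#' @param gene Locus symbol.
#' @return Character matrix with one row per engineered twin pair (columns
#'   `a`, `b`).
#' @export
twin_pairs <- function(spec, gene) {
  t <- seq_len(spec$n_exon23_twins)
  cbind(a = sprintf("%s*%02d:01", gene, 2L * t - 1L),
        b = sprintf("%s*%02d:01", gene, 2L * t))
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

sim_hap_reads <- function(seq_chr, n, read_len, err_rate) {
  L <- nchar(seq_chr)
  pos <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  reads <- substring(seq_chr, pos + 1L, pos + read_len)
  rev_sel <- strand == "-"
  if (any(rev_sel)) reads[rev_sel] <- rc_chr(reads[rev_sel])
  err_pos <- vector("list", n)
  hit <- which(stats::runif(n * read_len) < err_rate)
  if (length(hit)) {
    ri <- (hit - 1L) %/% read_len + 1L
    bp <- (hit - 1L) %% read_len + 1L
    for (k in seq_along(hit)) {
      cur <- substr(reads[ri[k]], bp[k], bp[k])
      sub <- BASES[((match(cur, BASES) - 1L + sample.int(3L, 1L)) %% 4L) + 1L]
      substr(reads[ri[k]], bp[k], bp[k]) <- sub
      err_pos[[ri[k]]] <- c(err_pos[[ri[k]]], bp[k])
    }
  }
  list(seq = reads, pos = pos, strand = strand, err_pos = err_pos)
}

#' Simulate diploid short reads with ground truth
#'
#' Reads are drawn uniformly along each haplotype of each genotype; the
#' per-haplotype read count is Poisson with mean
#' `coverage / 2 * L / read_len`, strands are unbiased, and substitution
#' errors are injected i.i.d. at `err_rate` with positions logged.  With
#' `paired = TRUE`, fragments of normally distributed length yield `/1`,
#' `/2` mate pairs (outer coordinates logged).  Deterministic given `seed`:
#' one pseudo-random stream, consumed in genotype-row then haplotype-slot
#' order.
#'
#' @param panel An `hla_panel`.
#' @param genotypes `data.frame` (`sample`, `gene`, `allele1`, `allele2`);
#'   all alleles must be in the panel.
#' @param coverage Target total depth per gene (both haplotypes).
#' @param read_len Read length in bases (at most the allele length).
#' @param err_rate Per-base substitution error rate.
#' @param paired Emit mate pairs instead of single-end reads.
#' @param insert_mean,insert_sd Fragment-length distribution for
#'   `paired = TRUE`.
#' @param seed Seed for the stream.
#' @return List with `reads` (`data.frame`: `id`, `sample`, `seq`) and
#'   `read_truth` (`id`, `sample`, `gene`, `allele`, `pos`, `strand`,
#'   `n_err`, `err_pos` comma-joined 1-based read coordinates).
#' @export
simulate_reads <- function(panel, genotypes, coverage = 30, read_len = 100L,
                           err_rate = 0.005, paired = FALSE,
                           insert_mean = 350, insert_sd = 30, seed = 1L) {
  stopifnot(coverage > 0, read_len >= 1L, err_rate >= 0, err_rate < 1)
  alleles <- unique(c(genotypes$allele1, genotypes$allele2))
  if (!all(alleles %in% names(panel$seq))) {
    stop("genotype alleles absent from panel: ",
         paste(setdiff(alleles, names(panel$seq)), collapse = ", "))
  }
  if (read_len > min(nchar(panel$seq[alleles]))) {
    stop("read_len exceeds an allele length")
  }
  with_seed(seed, {
    out_reads <- list()
    out_truth <- list()
    counter <- integer(0)
    for (r in seq_len(nrow(genotypes))) {
      smp <- genotypes$sample[r]
      if (!smp %in% names(counter)) counter[smp] <- 0L
      for (slot in 1:2) {
        allele <- genotypes[[paste0("allele", slot)]][r]
        seq_chr <- panel$seq[[allele]]
        L <- nchar(seq_chr)
        if (!paired) {
          n <- stats::rpois(1L, coverage / 2 * L / read_len)
          if (n == 0L) next
          h <- sim_hap_reads(seq_chr, n, read_len, err_rate)
          ids <- sprintf("%s:r%06d", smp, counter[[smp]] + seq_len(n))
          counter[[smp]] <- counter[[smp]] + n
          out_reads[[length(out_reads) + 1L]] <- data.frame(
            id = ids, sample = smp, seq = h$seq)
          out_truth[[length(out_truth) + 1L]] <- data.frame(
            id = ids, sample = smp, gene = genotypes$gene[r],
            allele = allele, pos = h$pos, strand = h$strand,
            n_err = lengths(h$err_pos),
            err_pos = vapply(h$err_pos, paste, character(1), collapse = ","))
        } else {
          n <- stats::rpois(1L, coverage / 4 * L / read_len)  # pairs
          if (n == 0L) next
          ins <- pmin(pmax(round(stats::rnorm(n, insert_mean, insert_sd)),
                           2L * read_len), L)
          start <- vapply(ins, function(s)
            sample.int(L - s + 1L, 1L) - 1L, integer(1))
          ids <- sprintf("%s:r%06d", smp, counter[[smp]] + seq_len(n))
          counter[[smp]] <- counter[[smp]] + n
          for (mate in 1:2) {
            mpos <- if (mate == 1L) start else start + ins - read_len
            seqs <- substring(seq_chr, mpos + 1L, mpos + read_len)
            if (mate == 2L) seqs <- rc_chr(seqs)
            err <- lapply(seq_len(n), function(k) {
              which(stats::runif(read_len) < err_rate)
            })
            for (k in seq_len(n)) {
              for (bp in err[[k]]) {
                cur <- substr(seqs[k], bp, bp)
                substr(seqs[k], bp, bp) <-
                  BASES[((match(cur, BASES) - 1L +
                            sample.int(3L, 1L)) %% 4L) + 1L]
              }
            }
            mid <- paste0(ids, "/", mate)
            out_reads[[length(out_reads) + 1L]] <- data.frame(
              id = mid, sample = smp, seq = seqs)
            out_truth[[length(out_truth) + 1L]] <- data.frame(
              id = mid, sample = smp, gene = genotypes$gene[r],
              allele = allele, pos = mpos,
              strand = if (mate == 1L) "+" else "-",
              n_err = lengths(err),
              err_pos = vapply(err, paste, character(1), collapse = ","))
          }
        }
      }
    }
    list(reads = do.call(rbind, c(out_reads, list(make.row.names = FALSE))),
         read_truth = do.call(rbind,
                              c(out_truth, list(make.row.names = FALSE))))
  })
}

#' Write reads as FASTQ (flat quality)
#' @param reads `data.frame` with `id` and `seq`.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                    strrep("I", nchar(reads$seq))), path)
  invisible(reads)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(ss), seq = as.character(ss))
}

#' Simulate a complete typing study
#'
#' Builds the panel from `spec`, draws diploid genotypes for `n_samples`
#' (per gene, two distinct alleles sampled uniformly without replacement —
#' or, with `twin_only = TRUE`, a homozygous genotype for a random member
#' of the gene's first engineered twin pair, the adversarial case for
#' exon-only references), and simulates reads for every sample.
#'
#' @param spec A [panel_spec()].
#' @param n_samples Number of diploid samples.
#' @param coverage,read_len,err_rate,paired Passed to [simulate_reads()].
#' @param twin_only Restrict truth to exon-identical twin alleles.
#' @param seed Seed for genotype drawing and read simulation (the panel
#'   uses `spec$seed`).
#' @return List with `panel`, `spec`, `truth` (typing `data.frame`),
#'   `reads` (named list: per sample a `data.frame` of `id`, `seq`),
#'   `read_truth`, and `coverage`.
#' @export
simulate_dataset <- function(spec = panel_spec(), n_samples = 50L,
                             coverage = 30, read_len = 100L,
                             err_rate = 0.005, paired = FALSE,
                             twin_only = FALSE, seed = 1L) {
  panel <- make_panel(spec)
  genes <- panel_genes(panel)
  truth <- with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_samples)) {
      smp <- sprintf("sim%03d", s)
      for (g in genes) {
        if (twin_only) {
          if (spec$n_exon23_twins < 1L) stop("no twin pairs in this spec")
          m <- sample(twin_pairs(spec, g)[1L, ], 1L)
          pair <- c(m, m)
        } else {
          cand <- names(panel$seq)[hla_gene(names(panel$seq)) == g]
          pair <- sort(sample(cand, 2L))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, gene = g, allele1 = pair[1], allele2 = pair[2])
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  sim <- simulate_reads(panel, truth, coverage = coverage,
                        read_len = read_len, err_rate = err_rate,
                        paired = paired, seed = seed + 1L)
  list(panel = panel, spec = spec, truth = truth,
       reads = split(sim$reads, sim$reads$sample),
       read_truth = sim$read_truth, coverage = coverage)
}
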