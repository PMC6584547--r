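# Independent oracles used across the suite.  Each deliberately avoids the
# code path it checks.

# random valid allele name for the parse/render round-trip property
random_allele_name <- function() {
  gene <- sample(c("A", "B", "C", "DRB1", "DQB1"), 1)
  nf <- sample(1:4, 1)
  fields <- vapply(seq_len(nf), function(i) {
    w <- sample(2:3, 1)
    paste(sample(0:9, w, replace = TRUE), collapse = "")
  }, character(1))
  suffix <- sample(c("", "N", "L", "S", "C", "A", "Q"), 1,
                   prob = c(0.7, rep(0.05, 6)))
  g <- sample(c(TRUE, FALSE), 1, prob = c(0.2, 0.8))
  paste0(gene, "*", paste(fields, collapse = ":"), suffix, if (g) "G")
}

# O(M^2) pairwise-identity partition over a gene's alleles
brute_partition <- function(panel, gene, features = exon23()) {
  alleles <- panel_alleles(panel)[hla_gene(panel_alleles(panel)) == gene]
  subs <- vapply(alleles, feature_subsequence, character(1),
                 panel = panel, features = features)
  assigned <- integer(length(alleles))
  gid <- 0L
  for (a in seq_along(alleles)) {
    if (assigned[a] > 0L) next
    gid <- gid + 1L
    assigned[a] <- gid
    if (a < length(alleles)) {
      for (b in (a + 1L):length(alleles)) {
        if (assigned[b] == 0L && subs[b] == subs[a]) assigned[b] <- gid
      }
    }
  }
  members <- lapply(split(alleles, assigned), sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  unname(members)
}

# exhaustive sliding-window ungapped aligner (oracle for naive_align)
brute_align_best <- function(read, ref, max_mm = Inf) {
  L <- nchar(read)
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else rc(read)
    sv <- strsplit(s, "")[[1]]
    for (p in 0:(nchar(ref) - L)) {
      mm <- sum(sv != strsplit(substr(ref, p + 1, p + L), "")[[1]])
      if (mm <= max_mm && (is.null(best) || mm < best$mm)) {
        best <- list(mm = mm, strand = strand, pos = p)
      }
    }
  }
  best
}

# exact posterior mean of theta for a 2-allele mixture with Beta(alpha0)
# prior: the marginal likelihood is a polynomial in t, so every posterior
# moment reduces to Beta-function integrals (independent of the VB path)
posterior_mean_exact_2 <- function(ll, alpha0) {
  co <- 1
  for (i in seq_len(nrow(ll))) {
    m <- max(ll[i, ])
    a <- exp(ll[i, 1] - m); b <- exp(ll[i, 2] - m)
    co <- b * c(co, 0) + (a - b) * c(0, co)   # multiply by (a t + b (1-t))
  }
  k <- seq_along(co) - 1
  num <- sum(co * exp(lbeta(alpha0 + k + 1, alpha0)))
  den <- sum(co * exp(lbeta(alpha0 + k, alpha0)))
  s1 <- num / den
  c(s1, 1 - s1)
}

# direct numerical maximisation of the observed-data log-likelihood over the
# simplex (oracle for EM); softmax parameterisation, multi-start optim
optim_mle_theta <- function(ll) {
  M <- ncol(ll)
  obj <- function(eta) {
    th <- exp(c(eta, 0)); th <- th / sum(th)
    s <- sweep(ll, 2, log(th), "+")
    m <- apply(s, 1, max)
    -sum(m + log(rowSums(exp(s - m))))
  }
  if (M == 1L) return(1)
  best <- NULL
  for (start in list(rep(0, M - 1), rep(1, M - 1), rep(-1, M - 1))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- exp(c(best$par, 0))
  th / sum(th)
}

# build an hla_evidence object from a dense log-likelihood matrix
toy_evidence <- function(ll, alleles = NULL, read_len = 100L) {
  N <- nrow(ll)
  if (is.null(alleles)) {
    alleles <- sprintf("A*%02d:01", seq_len(ncol(ll)))
  }
  reads <- sprintf("r%03d", seq_len(N))
  ent <- data.frame(read = rep(reads, each = ncol(ll)),
                    allele = rep(alleles, N),
                    log_lik = as.vector(t(ll)))
  hlacall:::new_evidence(ent, setNames(rep(read_len, N), reads), alleles)
}

# three-way calling rule re-evaluated from scratch (oracle for call_gene)
brute_call <- function(depths, gmd, tau, delta, resolution = 2L) {
  nm <- hla_truncate(names(depths), resolution)
  agg <- tapply(depths, nm, sum)
  ord <- order(-agg, names(agg))
  d1 <- agg[ord[1]]; n1 <- names(agg)[ord[1]]
  d2 <- if (length(agg) > 1) agg[ord[2]] else 0
  n2 <- if (length(agg) > 1) names(agg)[ord[2]] else n1
  lim <- delta * gmd / 2
  if (d1 < lim) return(c("fail", "fail"))
  if (d2 >= tau * d1 && d2 >= lim) return(sort(c(n1, n2)))
  c(n1, n1)
}
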