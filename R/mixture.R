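#' Fit the read-mixture abundance model over panel alleles
#'
#' The generative model treats every sequenced fragment as drawn from one of
#' the panel alleles: allele proportions `theta ~ Dirichlet(alpha0, ...,
#' alpha0)`; for fragment `i`, a latent source allele `a_i ~
#' Categorical(theta)`; the fragment's bases then yield the alignment
#' log-likelihood `ll[i, j]` stored in the evidence matrix.  Because HLA
#' alleles are extremely similar, most fragments align to many alleles and
#' the model's job is to apportion that multi-mapped evidence.
#'
#' Two fitting modes are provided:
#' \describe{
#'   \item{`"vb"`}{Mean-field variational Bayes with factorisation
#'     `q(z) q(theta)`.  Coordinate updates: responsibilities
#'     `z[i,j] propto exp(digamma(alpha[j]) - digamma(sum(alpha))) *
#'     exp(ll[i,j])` normalised per fragment, then
#'     `alpha[j] = alpha0 + sum_i z[i,j]`.  The evidence lower bound (ELBO)
#'     is non-decreasing across iterations.  A small `alpha0` (default 0.2)
#'     favours sparse solutions, appropriate when the true diploid mixture
#'     holds at most two alleles per gene among hundreds of candidates.}
#'   \item{`"em"`}{Maximum-likelihood EM on the same mixture
#'     (`z[i,j] propto theta[j] exp(ll[i,j])`,
#'     `theta[j] = sum_i z[i,j] / N`), used as an independent cross-check:
#'     the observed-data log-likelihood is concave in `theta`, so EM attains
#'     the global maximum.}
#' }
#'
#' Initialisation is deterministic (uniform responsibilities), so a fit is
#' exactly reproducible.  All per-fragment normalisations subtract the row
#' maximum before exponentiating, since likelihood ratios across alleles
#' span hundreds of log units.
#'
#' @param evidence An `hla_evidence` (see [align_reads()],
#'   [evidence_from_sam()]).
#' @param method `"vb"` (default) or `"em"`.
#' @param alpha0 Dirichlet prior concentration per allele (> 0).
#' @param tol Convergence tolerance on the mean absolute change of the
#'   variational parameters `alpha` (VB) or of `N * theta` (EM).
#' @param max_iter Iteration cap.
#' @param allele_lengths Optional named lengths (from [allele_lengths()]);
#'   when provided, per-allele normalised depths are computed as
#'   `sum_i z[i,j] * bases_i / L_j`.
#' @return An object of class `hla_mixture` with components `alleles`,
#'   `alpha` (posterior Dirichlet parameters), `expected_counts`
#'   (`sum_i z[i,j]`), `theta` (posterior mean proportions, summing to 1),
#'   `depth` (or `NULL`), `n_iter`, `converged`, `objective_trace` (ELBO or
#'   log-likelihood per iteration), `responsibilities` (sparse triplets) and
#'   `method`.
#' @examples
#' sim <- simulate_dataset(n_samples = 1, seed = 1)
#' ev <- align_reads(sim$reads[[1]], sim$panel)
#' fit <- hla_mixture(ev, allele_lengths = allele_lengths(sim$panel))
#' head(summary(fit), 4)
#' @export
hla_mixture <- function(evidence, method = c("vb", "em"), alpha0 = 0.2,
                        tol = 1e-6, max_iter = 1000L,
                        allele_lengths = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(evidence, "hla_evidence"),
            alpha0 > 0, tol > 0, max_iter >= 1L)
  ent <- evidence$entries
  if (!nrow(ent)) stop("empty evidence matrix")
  alleles <- evidence$alleles
  reads <- names(evidence$read_len)
  i <- match(ent$read, reads)
  j <- match(ent$allele, alleles)
  if (anyNA(j)) stop("evidence refers to alleles outside the panel universe")
  ll <- ent$log_lik
  N <- length(reads)
  M <- length(alleles)

  # z: responsibilities on the sparse triplet support, uniform per fragment
  n_cand <- tabulate(i, N)
  z <- 1 / n_cand[i]
  counts_at <- function(z) {
    cs <- numeric(M)
    agg <- rowsum(z, j)
    cs[as.integer(rownames(agg))] <- agg[, 1]
    cs
  }
  counts <- counts_at(z)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  theta <- NULL

  logsum_by_read <- function(s) {
    mx <- tapply(s, i, max)[as.character(seq_len(N))]
    mx <- unname(mx)
    e <- exp(s - mx[i])
    tot <- numeric(N)
    agg <- rowsum(e, i)
    tot[as.integer(rownames(agg))] <- agg[, 1]
    list(mx = mx, e = e, tot = tot)
  }

  if (method == "vb") {
    alpha <- alpha0 + counts
    repeat {
      iter <- iter + 1L
      elw <- digamma(alpha) - digamma(sum(alpha))   # E[log theta]
      s <- ll + elw[j]
      ls <- logsum_by_read(s)
      z <- ls$e / ls$tot[i]
      counts <- counts_at(z)
      alpha_new <- alpha0 + counts
      # ELBO with q(z) = z and q(theta) = Dir(alpha_new)
      elw2 <- digamma(alpha_new) - digamma(sum(alpha_new))
      ent_z <- -sum(z[z > 0] * log(z[z > 0]))
      kl_theta <- lgamma(sum(alpha_new)) - sum(lgamma(alpha_new)) -
        lgamma(M * alpha0) + M * lgamma(alpha0) +
        sum((alpha_new - alpha0) * elw2)
      elbo <- sum(z * ll) + sum(counts * elw2) + ent_z - kl_theta
      trace <- c(trace, elbo)
      delta <- mean(abs(alpha_new - alpha))
      alpha <- alpha_new
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    theta <- alpha / sum(alpha)
  } else {
    th <- rep(1 / M, M)
    repeat {
      iter <- iter + 1L
      s <- ll + log(pmax(th[j], 1e-300))
      ls <- logsum_by_read(s)
      z <- ls$e / ls$tot[i]
      counts <- counts_at(z)
      th_new <- counts / N
      loglik <- sum(ls$mx + log(ls$tot))
      trace <- c(trace, loglik)
      delta <- mean(abs(N * (th_new - th)))
      th <- th_new
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    theta <- th
    alpha <- alpha0 + counts
  }

  depth <- NULL
  if (!is.null(allele_lengths)) {
    if (!all(alleles %in% names(allele_lengths))) {
      stop("allele_lengths must cover every panel allele")
    }
    L <- as.numeric(allele_lengths[alleles])
    if (any(L <= 0)) stop("allele of length 0")
    bases <- as.numeric(evidence$read_len)[i] * z
    d <- numeric(M)
    agg <- rowsum(bases, j)
    d[as.integer(rownames(agg))] <- agg[, 1]
    depth <- stats::setNames(d / L, alleles)
  }

  structure(list(
    alleles = alleles,
    alpha = stats::setNames(alpha, alleles),
    expected_counts = stats::setNames(counts, alleles),
    theta = stats::setNames(theta / sum(theta), alleles),
    depth = depth,
    n_iter = iter, converged = converged,
    objective_trace = trace,
    responsibilities = data.frame(read = ent$read, allele = ent$allele,
                                  z = z),
    method = method, alpha0 = alpha0, tol = tol,
    n_fragments = N), class = "hla_mixture")
}

#' @export
print.hla_mixture <- function(x, ...) {
  cat(sprintf(
    "%s read-mixture fit: %d fragments, %d alleles; %d iteration(s), %s\n",
    toupper(x$method), x$n_fragments, length(x$alleles), x$n_iter,
    if (x$converged) "converged" else "iteration cap reached"))
  top <- utils::head(order(-x$expected_counts), 4L)
  cat("  top alleles by expected count:\n")
  for (t in top) {
    cat(sprintf("    %-14s count %8.1f  theta %.4f%s\n", x$alleles[t],
                x$expected_counts[t], x$theta[t],
                if (!is.null(x$depth)) sprintf("  depth %6.2f", x$depth[t])
                else ""))
  }
  invisible(x)
}

#' @method summary hla_mixture
#' @export
summary.hla_mixture <- function(object, ...) {
  df <- data.frame(allele = object$alleles,
                   alpha = unname(object$alpha),
                   expected_count = unname(object$expected_counts),
                   theta = unname(object$theta))
  if (!is.null(object$depth)) df$depth <- unname(object$depth)
  df <- df[order(-df$expected_count, df$allele), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @method coef hla_mixture
#' @export
coef.hla_mixture <- function(object, ...) object$theta

#' @method logLik hla_mixture
#' @export
logLik.hla_mixture <- function(object, ...) {
  structure(utils::tail(object$objective_trace, 1L),
            df = length(object$alleles) - 1L, class = "logLik")
}

#' @method plot hla_mixture
#' @export
plot.hla_mixture <- function(x, top = 10L, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
       xlab = "iteration",
       ylab = if (x$method == "vb") "ELBO" else "log-likelihood",
       main = "convergence", ...)
  ord <- utils::head(order(-x$expected_counts), top)
  graphics::barplot(x$expected_counts[ord], names.arg = x$alleles[ord],
                    las = 2, cex.names = 0.7, ylab = "expected fragments",
                    main = "top alleles")
  invisible(x)
}

#' Per-fragment responsibilities of a fitted mixture
#' @param fit An `hla_mixture`.
#' @return Sparse `data.frame` (`read`, `allele`, `z`); `z` sums to 1 within
#'   each fragment.
#' @export
responsibilities <- function(fit) {
  stopifnot(inherits(fit, "hla_mixture"))
  fit$responsibilities
}
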