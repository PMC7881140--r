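#' Principal component embedding of pooled samples
#'
#' Centered singular-value decomposition of the sample x site frequency
#' matrix, the standard visual check that replicate populations under the
#' same selective environment track each other while diverging from
#' controls. Missing frequencies are mean-imputed per site. With
#' `site_set = "extant"` only sites polymorphic at the first sampled
#' generation enter; `"all"` additionally keeps sites that arose later
#' (the two embeddings should be close when de novo sites are few).
#'
#' @param freqs a [to_frequencies()] tensor.
#' @param site_set `"extant"` (default) or `"all"`.
#' @return Object of class `"sample_embedding"`: `coordinates`
#'   (data.frame: replicate, generation, PC1..), `var_explained`, `sdev`.
#' @export
pca_samples <- function(freqs, site_set = c("extant", "all")) {
  stopifnot(inherits(freqs, "freq_tensor"))
  site_set <- match.arg(site_set)
  if (nrow(freqs$samples) < 3) stop("need >= 3 samples")
  f <- freqs$freq
  if (site_set == "extant") {
    g0 <- min(freqs$samples$generation)
    at0 <- freqs$samples$generation == g0
    m0 <- rowMeans(f[, at0, drop = FALSE], na.rm = TRUE)
    f <- f[!is.na(m0) & m0 > 0 & m0 < 1, , drop = FALSE]
  }
  if (nrow(f) < ncol(f))
    warning("fewer sites than samples; embedding is degenerate")
  mu <- rowMeans(f, na.rm = TRUE)
  for (j in seq_len(ncol(f))) f[is.na(f[, j]), j] <- mu[is.na(f[, j])]
  X <- t(f - mu)                      # samples x sites, centered
  sv <- svd(X)
  var_exp <- sv$d^2 / max(sum(sv$d^2), .Machine$double.eps)
  k <- min(5L, length(sv$d))
  coords <- as.data.frame(X %*% sv$v[, seq_len(k), drop = FALSE])
  names(coords) <- paste0("PC", seq_len(k))
  structure(list(
    coordinates = cbind(freqs$samples[, c("replicate", "generation")],
                        coords),
    var_explained = var_exp, sdev = sv$d / sqrt(max(1, nrow(X) - 1))),
    class = "sample_embedding")
}

#' @export
print.sample_embedding <- function(x, ...) {
  cat(sprintf("<sample_embedding> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$coordinates), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Allele-frequency spectrum in an interval
#'
#' Binned counts of polymorphic sites by pooled derived-allele frequency
#' (alternate allele as polarized at input; frequencies 0 and 1 excluded)
#' at one generation. Under neutrality the number of sites with i mutant
#' copies falls off as 1/i, so intermediate-frequency bins are well
#' populated; a selective sweep empties them.
#'
#' @param acm an [allele_counts()] object.
#' @param generation generation at which to pool counts over replicates.
#' @param interval optional interval (`chrom`, `start`, `end`, 0-based
#'   half-open); default all sites.
#' @param n_bins number of frequency bins on (0, 1).
#' @return data.frame with `bin_lo`, `bin_hi`, `mid`, `count`.
#' @export
afs <- function(acm, generation, interval = NULL, n_bins = 10) {
  stopifnot(inherits(acm, "allele_counts"))
  at <- acm$samples$generation == generation
  if (!any(at)) stop("generation ", generation, " not sampled")
  idx <- if (is.null(interval)) seq_len(nrow(acm$sites))
         else .sites_in_interval(acm$sites, interval)
  br <- seq(0, 1, length.out = n_bins + 1L)
  out <- data.frame(bin_lo = br[-length(br)], bin_hi = br[-1])
  out$mid <- (out$bin_lo + out$bin_hi) / 2
  if (!length(idx)) { out$count <- 0L; return(out) }
  a <- rowSums(acm$alt[idx, at, drop = FALSE])
  d <- a + rowSums(acm$ref[idx, at, drop = FALSE])
  p <- a[d > 0] / d[d > 0]
  p <- p[p > 0 & p < 1]
  out$count <- as.integer(table(cut(p, br, include.lowest = FALSE)))
  out
}

#' Between-generation divergence of a replicate population
#'
#' Distance between the genome-wide pooled frequency vectors of one
#' replicate at two generations; sites missing in either sample are
#' dropped pairwise. During an adaptive phase divergence accumulates much
#' faster than under post-fixation drift, so the ratio of early to late
#' divergence exceeds 1 in swept populations.
#'
#' @param freqs a [to_frequencies()] tensor.
#' @param replicate replicate id.
#' @param g_from,g_to sampled generations.
#' @param method `"euclidean"` (default) or `"mean_abs"` (mean |dp|).
#' @return Numeric scalar (with `n_sites` attribute).
#' @export
divergence <- function(freqs, replicate, g_from, g_to,
                       method = c("euclidean", "mean_abs")) {
  stopifnot(inherits(freqs, "freq_tensor"))
  method <- match.arg(method)
  sj <- which(freqs$samples$replicate == replicate)
  j1 <- sj[match(g_from, freqs$samples$generation[sj])]
  j2 <- sj[match(g_to, freqs$samples$generation[sj])]
  if (is.na(j1) || is.na(j2)) stop("generation not sampled for replicate")
  d <- freqs$freq[, j2] - freqs$freq[, j1]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no sites with data at both generations")
  out <- switch(method, euclidean = sqrt(sum(d^2)), mean_abs = mean(abs(d)))
  attr(out, "n_sites") <- length(d)
  out
}

#' @rdname divergence
#' @param span1,span2 `c(g_from, g_to)` pairs; the ratio is
#'   `divergence(span1) / divergence(span2)`.
#' @export
divergence_ratio <- function(freqs, replicate, span1, span2,
                             method = c("euclidean", "mean_abs")) {
  divergence(freqs, replicate, span1[1], span1[2], method) /
    divergence(freqs, replicate, span2[1], span2[2], method)
}
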