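#' Pooled allele-count time series
#'
#' `allele_counts()` builds the central container of the package: per-site,
#' per-sample reference/alternate read counts from pooled sequencing of an
#' evolving population, where each sample is one (replicate, generation)
#' pool. All downstream analyses (effective-population-size estimation, the
#' selection scan, the sweep classifier, diagnostics) consume this object.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (1-based
#'   integer position), `ref_allele`, `alt_allele` (single bases). Must be
#'   sorted by (chrom, pos) with no duplicated positions.
#' @param samples data.frame with columns `replicate` (character),
#'   `generation` (non-negative integer) and `pool_chromosomes` (number of
#'   chromosomes in the sequenced pool, e.g. 200 for a pool of 100 diploid
#'   individuals). Generations must be strictly increasing within each
#'   replicate, in sample order.
#' @param ref,alt integer matrices, `nrow(sites)` x `nrow(samples)`, of
#'   reference/alternate read counts. A cell with `ref + alt == 0` encodes
#'   missing data.
#'
#' @return An object of class `"allele_counts"`: a list with elements
#'   `sites`, `samples`, `ref`, `alt`.
#' @seealso [read_sync()], [to_frequencies()], [filter_sites()]
#' @export
allele_counts <- function(sites, samples, ref, alt) {
  sites <- as.data.frame(sites)
  samples <- as.data.frame(samples)
  stopifnot(
    all(c("chrom", "pos", "ref_allele", "alt_allele") %in% names(sites)),
    all(c("replicate", "generation") %in% names(samples))
  )
  if (is.null(samples$pool_chromosomes)) samples$pool_chromosomes <- NA_integer_
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (!identical(dim(ref), dim(alt)) ||
      nrow(ref) != nrow(sites) || ncol(ref) != nrow(samples))
    stop("count matrices must be nrow(sites) x nrow(samples)")
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stop("negative read counts")
  key <- order(sites$chrom, sites$pos)
  if (!identical(key, seq_len(nrow(sites))))
    stop("sites must be ordered by (chrom, pos)")
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicated (chrom, pos) in sites")
  for (r in unique(samples$replicate)) {
    g <- samples$generation[samples$replicate == r]
    if (any(diff(g) <= 0))
      stop("generations must be strictly increasing within replicate ", r)
  }
  rownames(sites) <- NULL; rownames(samples) <- NULL
  dimnames(ref) <- dimnames(alt) <-
    list(NULL, paste0(samples$replicate, "_g", samples$generation))
  structure(list(sites = sites, samples = samples, ref = ref, alt = alt),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %d sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  cat("  replicates:",
      paste(unique(x$samples$replicate), collapse = ", "), "\n")
  cat("  generations:",
      paste(sort(unique(x$samples$generation)), collapse = ", "), "\n")
  dp <- x$ref + x$alt
  cat(sprintf("  median depth %.0f; %.1f%% missing cells\n",
              stats::median(dp[dp > 0]), 100 * mean(dp == 0)))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset an allele_counts object
#'
#' `i` indexes sites, `j` samples; either may be logical or integer.
#' @param x an `allele_counts` object.
#' @param i,j site / sample indices.
#' @param ... ignored.
#' @export
`[.allele_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  allele_counts(x$sites[i, , drop = FALSE], x$samples[j, , drop = FALSE],
                x$ref[i, j, drop = FALSE], x$alt[i, j, drop = FALSE])
}

#' Combine per-replicate count matrices over shared sites
#'
#' Binds the samples of several `allele_counts` objects (typically one per
#' replicate population, e.g. from [pool_sequence()]) into one object. All
#' inputs must describe the identical site list.
#' @param ... `allele_counts` objects.
#' @return A single `allele_counts` object.
#' @export
combine_replicates <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "allele_counts"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "allele_counts")))
  s0 <- xs[[1]]$sites
  for (x in xs[-1])
    if (!identical(x$sites$chrom, s0$chrom) || !identical(x$sites$pos, s0$pos))
      stop("all inputs must share the same site list")
  allele_counts(s0,
                do.call(rbind, lapply(xs, `[[`, "samples")),
                do.call(cbind, lapply(xs, `[[`, "ref")),
                do.call(cbind, lapply(xs, `[[`, "alt")))
}

#' Convert counts to allele frequencies
#'
#' @param acm an [allele_counts()] object.
#' @return An object of class `"freq_tensor"`: list with `sites`, `samples`,
#'   `freq` (alt-allele frequency, `NA` where depth is 0) and `depth`
#'   matrices.
#' @examples
#' acm <- sim_example_counts(n_sites = 5, seed = 1)
#' f <- to_frequencies(acm)
#' range(f$freq, na.rm = TRUE)
#' @export
to_frequencies <- function(acm) {
  stopifnot(inherits(acm, "allele_counts"))
  depth <- acm$ref + acm$alt
  freq <- ifelse(depth > 0, acm$alt / depth, NA_real_)
  structure(list(sites = acm$sites, samples = acm$samples,
                 freq = freq, depth = depth),
            class = "freq_tensor")
}

#' @export
print.freq_tensor <- function(x, ...) {
  cat(sprintf("<freq_tensor> %d sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  invisible(x)
}

#' Filter sites on depth and extant polymorphism
#'
#' Retains sites with depth >= `min_depth` in every sample and, optionally,
#' minor-allele frequency >= `min_minor_freq` in the pooled counts at a
#' designated generation. With `complement = TRUE` the selection is inverted
#' into a de-novo candidate list: sites whose alternate allele is absent
#' from every replicate at the designated generation (despite coverage) but
#' observed at a later generation. "Extant" variation in an
#' evolve-and-resequence experiment is polymorphism already present at the
#' first sequenced generation; sweeps on alleles absent then are candidate
#' de novo events.
#'
#' @param acm an [allele_counts()] object.
#' @param min_depth minimum read depth required in all samples (default 10).
#' @param min_minor_freq minimum pooled minor-allele frequency at
#'   `require_polymorphic_at` (default 0, i.e. any observed polymorphism).
#' @param require_polymorphic_at generation at which the polymorphism
#'   condition is evaluated; defaults to the earliest sampled generation.
#' @param complement if `TRUE`, return the de novo candidates instead.
#' @return A filtered `allele_counts` object (always a subset of the input
#'   sites; the operation is idempotent).
#' @export
filter_sites <- function(acm, min_depth = 10, min_minor_freq = 0,
                         require_polymorphic_at = NULL, complement = FALSE) {
  stopifnot(inherits(acm, "allele_counts"),
            min_depth >= 0, min_minor_freq >= 0, min_minor_freq <= 0.5)
  gen <- require_polymorphic_at
  if (is.null(gen)) gen <- min(acm$samples$generation)
  at <- acm$samples$generation == gen
  if (!any(at)) stop("generation ", gen, " not present in any sample")
  depth <- acm$ref + acm$alt
  deep <- rowSums(depth >= min_depth) == ncol(depth)

  ref0 <- rowSums(acm$ref[, at, drop = FALSE])
  alt0 <- rowSums(acm$alt[, at, drop = FALSE])
  tot0 <- ref0 + alt0
  maf <- ifelse(tot0 > 0, pmin(alt0, ref0) / tot0, 0)

  if (!complement) {
    keep <- deep & maf >= min_minor_freq
    if (min_minor_freq > 0) keep <- keep & alt0 > 0 & ref0 > 0
  } else {
    later <- acm$samples$generation > gen
    alt_later <- if (any(later)) rowSums(acm$alt[, later, drop = FALSE]) else 0L
    keep <- deep & tot0 > 0 & alt0 == 0 & alt_later > 0
  }
  acm[keep, ]
}
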