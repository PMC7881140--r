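#' Read a Popoolation2 sync file
#'
#' Parses the standard sync dialect: tab-separated `chrom pos ref` followed
#' by one `A:T:C:G:N:del` count sextuple per sample column. Sites are
#' reduced to biallelic form: the reference allele is taken from column 3
#' and the alternate allele is the non-reference base with the highest
#' count summed over all samples (ties broken in base order A < C < G < T;
#' N and deletion counts are ignored).
#'
#' @param path path to the sync file.
#' @param sample_sheet data.frame (or path to a TSV) with columns `column`
#'   (1-based index among the count columns), `replicate`, `generation`,
#'   and optionally `pool_chromosomes`.
#' @return An [allele_counts()] object.
#' @export
read_sync <- function(path, sample_sheet) {
  sheet <- .read_sheet(sample_sheet)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty sync file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L)
    stop("ragged sync file: line ", which(ncols != ncols[1])[1])
  n_samples <- ncols[1] - 3L
  if (n_samples < 1L) stop("sync file has no count columns")
  if (!identical(sort(sheet$column), seq_len(n_samples)))
    stop("sample sheet lists ", nrow(sheet), " columns but sync file has ",
         n_samples, " (indices must be 1..", n_samples, ")")

  m <- matrix(unlist(fields), ncol = ncols[1], byrow = TRUE)
  chrom <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop("non-integer position at line ", which(is.na(pos))[1])
  ref <- toupper(m[, 3])
  bases <- c("A", "T", "C", "G")
  if (!all(ref %in% bases))
    stop("reference allele not in {A,C,G,T} at line ", which(!(ref %in% bases))[1])

  # counts[site, sample, base] from the A:T:C:G:N:del sextuples
  n_sites <- length(chrom)
  cnt <- array(0L, c(n_sites, n_samples, 4L))
  for (j in seq_len(n_samples)) {
    parts <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    bad <- lengths(parts) != 6L
    if (any(bad))
      stop("malformed count sextuple '", m[bad, 3L + j][1],
           "' at line ", which(bad)[1])
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v))
      stop("non-integer count at line ", which(is.na(rowSums(
        matrix(v, ncol = 6, byrow = TRUE)))) [1])
    v <- matrix(v, ncol = 6L, byrow = TRUE)
    cnt[, j, ] <- v[, 1:4]
  }

  ref_idx <- match(ref, bases)
  tot <- apply(cnt, c(1, 3), sum)              # site x base, pooled over samples
  tot[cbind(seq_len(n_sites), ref_idx)] <- -1L # exclude ref from alt choice
  # ties broken A<C<G<T: scan bases in that order, keep first maximum
  base_order <- match(c("A", "C", "G", "T"), bases)
  alt_idx <- base_order[max.col(tot[, base_order, drop = FALSE], "first")]

  ref_cnt <- alt_cnt <- matrix(0L, n_sites, n_samples)
  for (j in seq_len(n_samples)) {
    ref_cnt[, j] <- cnt[cbind(seq_len(n_sites), j, ref_idx)]
    alt_cnt[, j] <- cnt[cbind(seq_len(n_sites), j, alt_idx)]
  }

  o <- order(chrom, pos)
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicated (chrom, pos) in sync file")
  sheet <- sheet[order(match(sheet$replicate, unique(sheet$replicate)),
                       sheet$generation), ]
  sites <- data.frame(chrom = chrom[o], pos = pos[o],
                      ref_allele = ref[o], alt_allele = bases[alt_idx][o],
                      stringsAsFactors = FALSE)
  allele_counts(sites,
                data.frame(replicate = as.character(sheet$replicate),
                           generation = as.integer(sheet$generation),
                           pool_chromosomes = if (is.null(sheet$pool_chromosomes))
                             NA_integer_ else as.integer(sheet$pool_chromosomes),
                           stringsAsFactors = FALSE),
                ref_cnt[o, sheet$column, drop = FALSE],
                alt_cnt[o, sheet$column, drop = FALSE])
}

.read_sheet <- function(sample_sheet) {
  sheet <- if (is.character(sample_sheet))
    utils::read.table(sample_sheet, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else as.data.frame(sample_sheet)
  need <- c("column", "replicate", "generation")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  sheet$column <- as.integer(sheet$column)
  sheet
}

#' Write an allele_counts object as a sync file
#'
#' Canonical re-serialization: reference counts go to the reference base's
#' slot and alternate counts to the alternate base's slot of each
#' `A:T:C:G:N:del` sextuple; all other slots are zero. Samples are written
#' in their stored order, so `read_sync(write_sync(x), sheet)` reproduces
#' `x` exactly.
#'
#' @param acm an [allele_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(acm, path) {
  stopifnot(inherits(acm, "allele_counts"))
  bases <- c("A", "T", "C", "G")
  ri <- match(acm$sites$ref_allele, bases)
  ai <- match(acm$sites$alt_allele, bases)
  n <- nrow(acm$sites)
  cols <- character(nrow(acm$samples))
  out <- vector("list", nrow(acm$samples))
  for (j in seq_len(nrow(acm$samples))) {
    six <- matrix(0L, n, 6L)
    six[cbind(seq_len(n), ri)] <- acm$ref[, j]
    six[cbind(seq_len(n), ai)] <- acm$alt[, j]
    out[[j]] <- do.call(paste, c(as.data.frame(six), sep = ":"))
  }
  writeLines(do.call(paste, c(list(acm$sites$chrom, acm$sites$pos,
                                   acm$sites$ref_allele), out, sep = "\t")),
             path)
  invisible(path)
}

#' Read long-form allele counts
#'
#' Alternative input to sync: a TSV with columns `chrom, pos, replicate,
#' generation, ref_count, alt_count` (one row per site x sample), plus an
#' optional `pool_chromosomes` column.
#'
#' @param path path to the TSV (header required).
#' @param pool_chromosomes pool size applied to all samples when the file
#'   carries no `pool_chromosomes` column.
#' @return An [allele_counts()] object.
#' @export
read_counts_long <- function(path, pool_chromosomes = NA_integer_) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "replicate", "generation", "ref_count", "alt_count")
  if (!all(need %in% names(d)))
    stop("long-form counts need columns: ", paste(need, collapse = ", "))
  sites <- unique(d[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  sam <- unique(d[, c("replicate", "generation")])
  sam <- sam[order(match(sam$replicate, unique(sam$replicate)),
                   sam$generation), ]
  si <- match(paste(d$chrom, d$pos), paste(sites$chrom, sites$pos))
  sj <- match(paste(d$replicate, d$generation),
              paste(sam$replicate, sam$generation))
  ref <- alt <- matrix(0L, nrow(sites), nrow(sam))
  ref[cbind(si, sj)] <- as.integer(d$ref_count)
  alt[cbind(si, sj)] <- as.integer(d$alt_count)
  sam$pool_chromosomes <- if ("pool_chromosomes" %in% names(d))
    as.integer(d$pool_chromosomes[match(paste(sam$replicate, sam$generation),
                                        paste(d$replicate, d$generation))])
  else as.integer(pool_chromosomes)
  ra <- if ("ref_allele" %in% names(d))
    d$ref_allele[match(paste(sites$chrom, sites$pos), paste(d$chrom, d$pos))]
  else "A"
  aa <- if ("alt_allele" %in% names(d))
    d$alt_allele[match(paste(sites$chrom, sites$pos), paste(d$chrom, d$pos))]
  else "T"
  sites <- data.frame(sites, ref_allele = ra, alt_allele = aa,
                      stringsAsFactors = FALSE)
  allele_counts(sites, sam, ref, alt)
}

#' Genomic intervals
#'
#' Internal interval arithmetic uses 0-based half-open coordinates
#' (`start < end`); positions in sync files and printed reports are
#' 1-based. `genomic_intervals()` validates a data.frame of intervals;
#' `write_bed()` writes them in BED form (0-based half-open, the BED
#' convention).
#'
#' @param chrom character vector.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @return data.frame of class `"genomic_intervals"`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(start >= end)) stop("need 0 <= start < end")
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("genomic_intervals", "data.frame"))
}

#' @rdname genomic_intervals
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally a `name` and `score` column.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$score)) cols <- c(cols, list(intervals$score))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# merge overlapping/adjacent intervals within each chrom (0-based half-open)
merge_intervals <- function(chrom, start, end, gap = 0L) {
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  out <- list()
  i <- 1L
  while (i <= length(start)) {
    c0 <- chrom[i]; s0 <- start[i]; e0 <- end[i]
    j <- i + 1L
    while (j <= length(start) && chrom[j] == c0 && start[j] <= e0 + gap) {
      e0 <- max(e0, end[j]); j <- j + 1L
    }
    out[[length(out) + 1L]] <- data.frame(chrom = c0, start = s0, end = e0,
                                          stringsAsFactors = FALSE)
    i <- j
  }
  do.call(rbind, out)
}
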