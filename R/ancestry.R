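#' Build a complete-case AIM genotype matrix across labeled cohorts
#'
#' Extracts the requested ancestry-informative markers (AIMs) from each
#' cohort, merges samples across cohorts, and drops any AIM with a missing
#' genotype in any sample, so the result is complete-case by construction.
#'
#' @param cohorts Named list of `genotype_matrix` objects; names are the
#'   population labels assigned to each cohort's samples.
#' @param aims Character vector of AIM rsIDs.
#' @return An object of class `aim_matrix`: `codes` (samples x AIMs, no
#'   missing entries), `rsids`, `sample_ids`, `populations`, and `dropped`
#'   (AIMs removed for missingness or absence).
#' @export
build_aim_matrix <- function(cohorts, aims) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L,
            !is.null(names(cohorts)), length(aims) >= 1L)
  aims <- unique(as.character(aims))
  per <- lapply(cohorts, function(gm) {
    stopifnot(inherits(gm, "genotype_matrix"))
    idx <- match(aims, gm$sites$rsid)
    found <- which(!is.na(idx))
    m <- matrix(NA_integer_, nrow = length(gm$sample_ids), ncol = length(aims),
                dimnames = list(gm$sample_ids, aims))
    m[, found] <- gm$codes[, idx[found], drop = FALSE]
    m
  })
  codes <- do.call(rbind, per)
  populations <- rep(names(cohorts),
                     vapply(per, nrow, integer(1L)))
  complete <- colSums(is.na(codes)) == 0L
  dropped <- aims[!complete]
  codes <- codes[, complete, drop = FALSE]
  if (ncol(codes) == 0L) {
    stop("no AIMs with complete genotypes across the merged cohorts")
  }
  structure(
    list(codes = codes, rsids = colnames(codes),
         sample_ids = rownames(codes), populations = populations,
         dropped = dropped),
    class = "aim_matrix"
  )
}

#' @export
print.aim_matrix <- function(x, ...) {
  cat(sprintf(
    "aim_matrix: %d samples x %d complete-case AIMs (%d dropped), %d populations\n",
    nrow(x$codes), ncol(x$codes), length(x$dropped),
    length(unique(x$populations))
  ))
  invisible(x)
}

#' PCA of alternate-allele counts
#'
#' Principal component analysis of the AIM dosage matrix. Columns are
#' centered (not scaled) before decomposition. For reproducible plots the
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive. A constant matrix yields all-zero coordinates rather than an
#' error.
#'
#' @param x An `aim_matrix` (or plain numeric matrix, samples in rows).
#' @param k Number of components (default 2; must not exceed either
#'   dimension).
#' @return List with `scores` (samples x k), `var_fraction` (length k,
#'   non-increasing, summing to <= 1), `loadings`, and `populations` when
#'   available.
#' @export
pca_genotypes <- function(x, k = 2L) {
  codes <- if (inherits(x, "aim_matrix")) x$codes else as.matrix(x)
  pops <- if (inherits(x, "aim_matrix")) x$populations else NULL
  k <- as.integer(k)
  stopifnot(nrow(codes) >= 2L, ncol(codes) >= 2L,
            k >= 1L, k <= min(dim(codes)))
  centered <- scale(codes, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2)
  if (total_var < .Machine$double.eps) {
    return(list(
      scores = matrix(0, nrow(codes), k,
                      dimnames = list(rownames(codes),
                                      paste0("PC", seq_len(k)))),
      var_fraction = rep(0, k),
      loadings = matrix(0, ncol(codes), k),
      populations = pops
    ))
  }
  fit <- stats::prcomp(codes, center = TRUE, scale. = FALSE)
  kk <- min(k, ncol(fit$rotation))
  scores <- fit$x[, seq_len(kk), drop = FALSE]
  loadings <- fit$rotation[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (kk < k) {
    scores <- cbind(scores, matrix(0, nrow(scores), k - kk))
    loadings <- cbind(loadings, matrix(0, nrow(loadings), k - kk))
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  var_fraction <- c(fit$sdev^2 / sum(fit$sdev^2), rep(0, k))[seq_len(k)]
  list(scores = scores, var_fraction = var_fraction,
       loadings = loadings, populations = pops)
}

#' Per-population AIM allele frequencies for tree/admixture tools
#'
#' @param x An `aim_matrix`.
#' @param grouping Population label per sample; defaults to the labels
#'   stored in `x`.
#' @return Data frame, one row per population, one column per AIM, entries
#'   being alternate-allele frequencies in `[0, 1]`.
#' @export
export_population_frequencies <- function(x, grouping = NULL) {
  stopifnot(inherits(x, "aim_matrix"))
  grouping <- if (is.null(grouping)) x$populations else as.character(grouping)
  stopifnot(length(grouping) == nrow(x$codes))
  if (any(table(grouping) < 1L)) stop("every population needs >= 1 sample")
  sums <- rowsum(x$codes, grouping)
  sizes <- as.integer(table(grouping)[rownames(sums)])
  freq <- sums / (2 * sizes)
  out <- as.data.frame(freq)
  out <- cbind(population = rownames(sums), out)
  rownames(out) <- NULL
  out
}
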