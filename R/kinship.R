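# Pairwise-mismatch kinship estimation on pseudohaploid genotypes.
#
# For two pseudohaploid genomes the probability that their sampled alleles
# differ at a site is (1 - phi) * B, where phi is the kinship coefficient
# and B the mismatch rate of an unrelated pair in the same cohort. The
# normalized score norm = pmr / B therefore has expectation 1 - phi:
# 0.5 for the same individual (or monozygotic twins), 0.75 for first-degree
# pairs (parent-offspring, full siblings, dizygotic twins), 0.875 for
# second-degree pairs, 1 for unrelated pairs. Degree classes are cut at the
# midpoints between those expectations. Uncertainty comes from a delete-one
# block jackknife over contiguous 20 Mb windows.

#' Default degree-class cutoffs on the normalized mismatch score
#'
#' Midpoints of the expected scores \{0.5, 0.75, 0.875, 1\} for
#' identical/first/second/unrelated. Intervals are closed on the lower side:
#' norm < 0.625 is identical/twin, [0.625, 0.8125) first degree,
#' [0.8125, 0.90625) second degree, >= 0.90625 unrelated.
#' @export
default_degree_cutoffs <- function() {
  c(identical = 0.625, first = 0.8125, second = 0.90625)
}

block_id <- function(chromosome, position, block_size = 2e7) {
  paste0(chromosome, ":", (as.numeric(position) - 1) %/% block_size)
}

#' Pairwise mismatch rate between two pseudohaploid genomes
#'
#' Counts sites where both samples have non-missing calls (overlap) and the
#' fraction of those where the calls disagree. Per-block mismatch/overlap
#' counts over contiguous 20 Mb windows are retained for the jackknife.
#'
#' @param x a \code{\link{pseudohaploid_matrix}}.
#' @param a,b sample identifiers, \code{a != b} (pass the same matrix row
#'   twice under different ids to probe the identical-individual expectation).
#' @param block_size jackknife window size in bp (default 20 Mb).
#' @return list with \code{pair}, \code{overlap}, \code{mismatch},
#'   \code{pmr} (NA when overlap is 0) and a \code{blocks} data.frame of
#'   per-window counts (empty windows dropped).
#' @export
pairwise_mismatch <- function(x, a, b, block_size = 2e7) {
  stopifnot(inherits(x, "pseudohaploid_matrix"))
  if (a == b) stop("a and b must be different samples", call. = FALSE)
  for (s in c(a, b)) {
    if (!s %in% x$samples) stop("sample not in matrix: ", s, call. = FALSE)
  }
  ca <- x$calls[match(a, x$samples), ]
  cb <- x$calls[match(b, x$samples), ]
  both <- ca != 9L & cb != 9L
  mism <- both & (ca != cb)
  overlap <- sum(both)
  bid <- block_id(x$snps$chromosome, x$snps$position, block_size)
  ov_b <- tapply(both, bid, sum)
  mm_b <- tapply(mism, bid, sum)
  keep <- ov_b > 0
  blocks <- data.frame(block = names(ov_b)[keep],
                       overlap = as.integer(ov_b[keep]),
                       mismatch = as.integer(mm_b[keep]),
                       stringsAsFactors = FALSE)
  rownames(blocks) <- NULL
  list(pair = sort(c(a, b)), overlap = overlap, mismatch = sum(mism),
       pmr = if (overlap > 0) sum(mism) / overlap else NA_real_,
       blocks = blocks)
}

#' Background (unrelated-pair) mismatch rate
#'
#' In \code{"median"} mode the background is the median raw mismatch rate
#' over pairs with sufficient overlap, assuming the cohort is mostly
#' unrelated; a warning recommends \code{"supplied"} mode when more than
#' half the pairs later classify as related. In \code{"supplied"} mode the
#' given expected-unrelated rate is returned unchanged.
#'
#' @param pmrs numeric vector of eligible raw mismatch rates.
#' @param mode \code{"median"} or \code{"supplied"}.
#' @param value the expected unrelated pmr for \code{"supplied"} mode.
#' @return background rate B > 0.
#' @export
background_rate <- function(pmrs, mode = c("median", "supplied"),
                            value = NULL) {
  mode <- match.arg(mode)
  if (mode == "supplied") {
    if (is.null(value) || !is.finite(value) || value <= 0) {
      stop("supplied background must be a positive number", call. = FALSE)
    }
    return(value)
  }
  pmrs <- pmrs[is.finite(pmrs)]
  if (length(pmrs) == 0) {
    stop("no pairs with sufficient overlap to estimate a background rate",
         call. = FALSE)
  }
  b <- stats::median(pmrs)
  if (b <= 0) {
    stop("background mismatch rate is zero; cohort cannot be all identical",
         call. = FALSE)
  }
  b
}

#' Classify relatedness degree from a normalized mismatch score
#'
#' @param norm normalized score (pmr / background).
#' @param cutoffs named vector as \code{\link{default_degree_cutoffs}}.
#' @return one of \code{"identical/twin"}, \code{"first"}, \code{"second"},
#'   \code{"unrelated"}.
#' @export
classify_degree <- function(norm, cutoffs = default_degree_cutoffs()) {
  vapply(norm, function(v) {
    if (!is.finite(v)) return("insufficient")
    if (v < cutoffs[["identical"]]) "identical/twin"
    else if (v < cutoffs[["first"]]) "first"
    else if (v < cutoffs[["second"]]) "second"
    else "unrelated"
  }, character(1))
}

#' Delete-one-block jackknife SE of the normalized score
#'
#' Recomputes the pooled mismatch rate with each 20 Mb block left out in
#' turn and returns the jackknife standard error of \code{pmr / background}.
#' With fewer than two non-empty blocks the SE is NA (the degree is still
#' assigned from the point estimate).
#'
#' @param blocks per-block counts from \code{\link{pairwise_mismatch}}.
#' @param background background rate B used for normalization.
#' @return standard error (>= 0) or NA.
#' @export
jackknife_se <- function(blocks, background = 1) {
  blocks <- blocks[blocks$overlap > 0, , drop = FALSE]
  g <- nrow(blocks)
  if (g < 2) return(NA_real_)
  tot_m <- sum(blocks$mismatch)
  tot_o <- sum(blocks$overlap)
  loo <- (tot_m - blocks$mismatch) / (tot_o - blocks$overlap)
  loo <- loo[is.finite(loo)]
  g <- length(loo)
  if (g < 2) return(NA_real_)
  se_pmr <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  se_pmr / background
}

#' All-pairs kinship estimation
#'
#' Evaluates every unordered sample pair: raw mismatch rate, overlap,
#' normalized score against the cohort background, block-jackknife SE and
#' degree class. Pairs with overlap below \code{min_overlap} are reported
#' \code{"insufficient"} and excluded from the background estimate.
#'
#' @param x a \code{\link{pseudohaploid_matrix}} with >= 2 samples.
#' @param min_overlap minimum joint non-missing sites (default 1000).
#' @param background_mode \code{"median"} (cohort median) or
#'   \code{"supplied"}.
#' @param background_value expected unrelated pmr for supplied mode.
#' @param cutoffs degree cutoffs (see \code{\link{default_degree_cutoffs}}).
#' @param block_size jackknife window in bp.
#' @return data.frame of kinship estimates (one row per pair) with the
#'   background rate as attribute \code{"background"}.
#' @export
kin_matrix <- function(x, min_overlap = 1000,
                       background_mode = c("median", "supplied"),
                       background_value = NULL,
                       cutoffs = default_degree_cutoffs(),
                       block_size = 2e7) {
  stopifnot(inherits(x, "pseudohaploid_matrix"))
  background_mode <- match.arg(background_mode)
  n <- length(x$samples)
  if (n < 2) stop("at least 2 samples are required", call. = FALSE)
  pairs <- utils::combn(x$samples, 2, simplify = FALSE)
  raw <- lapply(pairs, function(p) {
    pairwise_mismatch(x, p[1], p[2], block_size = block_size)
  })
  pmrs <- vapply(raw, function(r) r$pmr, numeric(1))
  overlaps <- vapply(raw, function(r) r$overlap, numeric(1))
  eligible <- is.finite(pmrs) & overlaps >= min_overlap
  bg <- background_rate(pmrs[eligible], mode = background_mode,
                        value = background_value)
  out <- do.call(rbind, lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    ok <- eligible[i]
    norm <- if (ok) r$pmr / bg else NA_real_
    data.frame(sample_a = r$pair[1], sample_b = r$pair[2],
               overlap = r$overlap, pmr = r$pmr, norm = norm,
               se = if (ok) jackknife_se(r$blocks, bg) else NA_real_,
               degree = if (ok) classify_degree(norm, cutoffs)
                        else "insufficient",
               stringsAsFactors = FALSE)
  }))
  related <- out$degree %in% c("identical/twin", "first", "second")
  if (sum(eligible) > 0 && mean(related[eligible]) > 0.5) {
    warning("more than half of the eligible pairs classify as related; ",
            "the cohort violates the mostly-unrelated assumption - check ",
            "the background rate (consider background_mode = \"supplied\" ",
            "with an external unrelated-pair expectation)", call. = FALSE)
  }
  attr(out, "background") <- bg
  class(out) <- c("kinship_estimates", "data.frame")
  out
}

#' Relatedness network from kinship estimates
#'
#' Builds an undirected graph whose edges are the pairs classified at
#' second degree or closer; unrelated and insufficient pairs are excluded.
#'
#' @param estimates result of \code{\link{kin_matrix}}.
#' @param nodes optional full node set (defaults to all samples seen in the
#'   estimates, so isolated samples stay in the graph).
#' @return an \code{igraph} object with edge attributes \code{degree},
#'   \code{norm}, \code{se}.
#' @export
build_network <- function(estimates, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- unique(c(estimates$sample_a, estimates$sample_b))
  }
  keep <- estimates$degree %in% c("identical/twin", "first", "second")
  edges <- estimates[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("sample_a", "sample_b", "degree", "norm", "se")],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g
}
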