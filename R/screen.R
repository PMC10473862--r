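# Damage-aware variant panel screening.
#
# Ancient libraries carry post-mortem C>T / G>A deamination artifacts, so a
# transition supported by very few reads is indistinguishable from damage.
# The screen therefore excludes low-coverage transition hits unless the same
# allele is seen in more than one sample or an explicit phenotype
# corroboration (e.g. skeletal features consistent with the condition) is
# supplied. Transversions cannot be produced by deamination and are never
# excluded by this filter.

#' Screen one or more samples' pileup evidence against a variant panel
#'
#' Joins pileup records to panel sites on (chromosome, position). A panel
#' site with read evidence but a conflicting ref allele is skipped with a
#' warning. Sites with \code{alt_depth > 0} become candidate hits
#' (status \code{"retained"} pending \code{\link{apply_damage_filter}});
#' sites with evidence but no alt reads are \code{"no_call"}.
#'
#' @param pileup pileup data.frame (see \code{\link{read_pileup}}); may
#'   contain several samples.
#' @param panel panel data.frame (see \code{\link{read_panel}}).
#' @return data.frame of variant hits: sample, panel annotation, depth,
#'   alt_depth, allele_fraction, flags (comma-separated), status.
#' @export
screen_sample <- function(pileup, panel) {
  key_pu <- paste(pileup$chromosome, pileup$position)
  key_pn <- paste(panel$chromosome, panel$position)
  idx <- match(key_pu, key_pn)
  on_panel <- !is.na(idx)
  pu <- pileup[on_panel, , drop = FALSE]
  pn <- panel[idx[on_panel], , drop = FALSE]

  conflict <- pu$ref != pn$ref
  if (any(conflict)) {
    warning(sprintf(
      "%d pileup record(s) with ref allele conflicting with the panel ",
      sum(conflict)), "(e.g. ", pu$chromosome[conflict][1], ":",
      pu$position[conflict][1], "); site(s) skipped", call. = FALSE)
    pu <- pu[!conflict, , drop = FALSE]
    pn <- pn[!conflict, , drop = FALSE]
  }
  hits <- data.frame(
    sample = pu$sample,
    snp_id = pn$snp_id, chromosome = pn$chromosome, position = pn$position,
    ref = pn$ref, alt = pn$alt, mutation_class = pn$mutation_class,
    significance = pn$significance, condition = pn$condition,
    depth = pu$depth, alt_depth = pu$alt_depth,
    allele_fraction = ifelse(pu$depth > 0, pu$alt_depth / pu$depth,
                             NA_real_),
    flags = rep("", nrow(pu)),
    status = ifelse(pu$alt_depth > 0, "retained", "no_call"),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$sample, chromosome_rank(hits$chromosome),
                     hits$position), ]
  rownames(hits) <- NULL
  class(hits) <- c("variant_hits", "data.frame")
  hits
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ","), function(f) flag %in% f, logical(1))
}

add_flag <- function(flags, flag, where) {
  parts <- strsplit(flags, ",")
  out <- vapply(seq_along(parts), function(i) {
    f <- setdiff(parts[[i]], "")
    if (where[i]) f <- union(f, flag)
    paste(f, collapse = ",")
  }, character(1))
  out
}

#' Apply the damage-aware retention filter
#'
#' A transition hit with \code{0 < alt_depth < min_alt_reads} is flagged
#' \code{low_coverage_transition} and excluded, unless corroborated:
#' with \code{cross_sample = TRUE} an identical panel allele carried by at
#' least two samples is retained (\code{multi_sample_corroborated}), and an
#' explicit per-hit override (sample + snp_id) retains it as
#' \code{phenotype_corroborated}. Transversions are never excluded. The
#' filter recomputes flags from scratch, so applying it twice equals
#' applying it once, and raising \code{min_alt_reads} can only shrink the
#' retained set.
#'
#' @param hits variant hits from \code{\link{screen_sample}} (all samples
#'   of the cohort together, so cross-sample corroboration can be seen).
#' @param min_alt_reads minimum alt reads for an uncorroborated transition
#'   (default 2; a single read hit is excluded).
#' @param cross_sample allow corroboration by a second sample carrying the
#'   same allele.
#' @param overrides optional data.frame (sample, snp_id) of
#'   phenotype-corroborated hits.
#' @param min_depth optional additional total-depth requirement for
#'   transition hits (disabled by default).
#' @return hits with final \code{status} and \code{flags}.
#' @export
apply_damage_filter <- function(hits, min_alt_reads = 2,
                                cross_sample = TRUE, overrides = NULL,
                                min_depth = NULL) {
  flags <- rep("", nrow(hits))
  status <- ifelse(hits$alt_depth > 0, "retained", "no_call")

  is_candidate <- hits$alt_depth > 0
  low_transition <- is_candidate & hits$mutation_class == "transition" &
    (hits$alt_depth < min_alt_reads |
       (!is.null(min_depth) & hits$depth < (min_depth %||% 0)))

  allele_key <- paste(hits$chromosome, hits$position, hits$alt)
  carriers <- tapply(is_candidate, allele_key, sum)
  multi <- is_candidate & carriers[allele_key] >= 2

  pheno <- rep(FALSE, nrow(hits))
  if (!is.null(overrides) && nrow(overrides) > 0) {
    okey <- paste(overrides$sample, overrides$snp_id)
    pheno <- paste(hits$sample, hits$snp_id) %in% okey
  }

  flags <- add_flag(flags, "low_coverage_transition", low_transition)
  rescued_multi <- low_transition & cross_sample & multi
  rescued_pheno <- low_transition & pheno
  flags <- add_flag(flags, "multi_sample_corroborated", rescued_multi)
  flags <- add_flag(flags, "phenotype_corroborated", rescued_pheno)
  status[low_transition & !(rescued_multi | rescued_pheno)] <- "excluded"

  hits$flags <- flags
  hits$status <- status
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize screened hits per sample and condition
#'
#' One row per (sample, condition) with retained / excluded / no-call
#' counts and the strongest retained hit (highest alt_depth, ties by allele
#' fraction then panel order). Ordering is deterministic.
#'
#' @param hits filtered hits from \code{\link{apply_damage_filter}}.
#' @return summary data.frame.
#' @export
summarize_report <- function(hits) {
  empty <- data.frame(sample = character(0), condition = character(0),
                      retained = integer(0), excluded = integer(0),
                      no_call = integer(0), top_hit = character(0),
                      top_alt_depth = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  key <- interaction(hits$sample, hits$condition, drop = TRUE)
  rows <- lapply(split(hits, key), function(h) {
    ret <- h[h$status == "retained", , drop = FALSE]
    top <- if (nrow(ret) > 0) {
      ret[order(-ret$alt_depth, -ret$allele_fraction), , drop = FALSE][1, ]
    } else NULL
    data.frame(sample = h$sample[1], condition = h$condition[1],
               retained = sum(h$status == "retained"),
               excluded = sum(h$status == "excluded"),
               no_call = sum(h$status == "no_call"),
               top_hit = if (is.null(top)) NA_character_ else top$snp_id,
               top_alt_depth = if (is.null(top)) NA_integer_
                               else top$alt_depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample, out$condition), ]
  rownames(out) <- NULL
  out
}
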