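# Coverage-based ploidy estimation: per-chromosome normalized coverage
# ratios z-scored against a set of reference genomes, copy number by
# rounding per-copy ratios, karyotype assembly from gonosomal copies.
#
# The ratio for chromosome c is the per-site read rate on c divided by the
# autosome-wide per-site read rate, so a disomic autosome sits at 1, a
# single-copy X at 0.5, a trisomic chromosome at 1.5. References (declared
# XX or XY) provide a per-copy mean and SD for every chromosome; a test
# sample's copy number is its ratio divided by the per-copy mean, rounded.

#' Construct a per-chromosome depth table
#'
#' @param sample sample identifier.
#' @param chrom chromosome labels; all 22 autosomes must be present, X and Y
#'   are optional but required for karyotype calls.
#' @param reads read counts over panel sites per chromosome (>= 0).
#' @param sites panel site counts per chromosome (> 0).
#' @return a \code{depth_table}: data.frame (chromosome, reads, sites) with
#'   the sample id and mean autosomal coverage as attributes.
#' @export
depth_table <- function(sample, chrom, reads, sites) {
  chrom <- normalize_chromosome(chrom)
  reads <- as.numeric(reads)
  sites <- as.numeric(sites)
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome in depth table", call. = FALSE)
  }
  if (any(reads < 0)) stop("reads must be >= 0", call. = FALSE)
  if (any(sites <= 0)) stop("sites must be > 0", call. = FALSE)
  missing_auto <- setdiff(AUTOSOMES, chrom)
  if (length(missing_auto) > 0) {
    stop("depth table lacks autosome(s): ",
         paste(missing_auto, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(chromosome = chrom, reads = reads, sites = sites,
                  stringsAsFactors = FALSE)
  d <- d[order(chromosome_rank(d$chromosome)), ]
  rownames(d) <- NULL
  auto <- d$chromosome %in% AUTOSOMES
  attr(d, "sample") <- as.character(sample)
  attr(d, "mean_coverage") <- sum(d$reads[auto]) / sum(d$sites[auto])
  class(d) <- c("depth_table", "data.frame")
  d
}

#' Normalized per-chromosome coverage ratios
#'
#' \code{ratio_c = (reads_c / sites_c) / (sum(autosomal reads) /
#' sum(autosomal sites))}. The site-weighted mean autosomal ratio is 1 by
#' construction. Ratios are scale invariant: multiplying all read counts by
#' a constant leaves them unchanged.
#'
#' @param depth a \code{\link{depth_table}}.
#' @return named numeric vector chromosome -> ratio.
#' @export
normalize_depth <- function(depth) {
  stopifnot(inherits(depth, "depth_table"))
  auto <- depth$chromosome %in% AUTOSOMES
  rate <- sum(depth$reads[auto]) / sum(depth$sites[auto])
  if (rate <= 0) {
    stop("zero autosomal reads: insufficient data for coverage ",
         "normalization", call. = FALSE)
  }
  stats::setNames((depth$reads / depth$sites) / rate, depth$chromosome)
}

#' Parse a karyotype string into per-chromosome copy numbers
#'
#' Accepts a gonosomal token (\code{XX}, \code{XY}, \code{X0}, \code{XXY},
#' \code{XYY}, \code{XXX}, ...) optionally followed by autosomal gains or
#' losses, e.g. \code{"XY+21"} (trisomy 21 in a male) or \code{"XX-18"}.
#' \code{"trisomy-21"} is accepted as an alias for \code{"XX+21"}.
#'
#' @param karyotype karyotype string.
#' @return named numeric vector of copy numbers for chromosomes 1-22, X, Y.
#' @export
parse_karyotype <- function(karyotype) {
  kt <- gsub(" ", "", as.character(karyotype))
  if (tolower(kt) == "trisomy-21") kt <- "XX+21"
  copies <- stats::setNames(rep(2, 24), c(AUTOSOMES, GONOSOMES))
  parts <- regmatches(kt, regexec("^([XY0]+)((?:[+-](?:[0-9]+))*)$", kt))[[1]]
  if (length(parts) == 0 || !nzchar(parts[2])) {
    stop("cannot parse karyotype: ", karyotype, call. = FALSE)
  }
  gono <- strsplit(parts[2], "")[[1]]
  copies["X"] <- sum(gono == "X")
  copies["Y"] <- sum(gono == "Y")
  if (nzchar(parts[3])) {
    ops <- regmatches(parts[3], gregexpr("[+-][0-9]+", parts[3]))[[1]]
    for (op in ops) {
      chr <- substring(op, 2)
      if (!chr %in% AUTOSOMES) {
        stop("unknown autosome in karyotype: ", chr, call. = FALSE)
      }
      copies[chr] <- copies[chr] + if (substring(op, 1, 1) == "+") 1 else -1
    }
  }
  if (any(copies < 0)) stop("negative copy number in ", karyotype,
                            call. = FALSE)
  copies
}

#' Build per-copy reference coverage statistics
#'
#' For every chromosome the declared-normal reference genomes (XX or XY)
#' contribute their normalized ratio divided by the copy number their
#' karyotype implies, giving per-copy mean and SD that serve any test
#' karyotype. Y statistics therefore come only from XY references.
#'
#' @param refs list of \code{\link{depth_table}} objects.
#' @param ref_karyotypes named character vector sample -> "XX" or "XY".
#' @return \code{reference_stats}: data.frame with \code{chromosome},
#'   \code{per_copy_mean}, \code{per_copy_sd}, \code{n_ref}.
#' @export
build_reference_stats <- function(refs, ref_karyotypes) {
  if (inherits(refs, "depth_table")) refs <- list(refs)
  if (length(refs) < 2) {
    stop("at least 2 reference genomes are required", call. = FALSE)
  }
  per_copy <- lapply(refs, function(d) {
    id <- attr(d, "sample")
    kt <- ref_karyotypes[[id]]
    if (is.null(kt) || is.na(kt)) {
      stop("no declared karyotype for reference sample ", id, call. = FALSE)
    }
    if (!kt %in% c("XX", "XY")) {
      stop("reference sample ", id, " must be declared XX or XY, got ", kt,
           call. = FALSE)
    }
    copies <- parse_karyotype(kt)
    ratio <- normalize_depth(d)
    pc <- ratio / copies[names(ratio)]
    pc[copies[names(ratio)] == 0] <- NA_real_  # Y in XX refs: uninformative
    pc
  })
  chroms <- unique(unlist(lapply(per_copy, names)))
  chroms <- chroms[order(chromosome_rank(chroms))]
  stats_rows <- lapply(chroms, function(ch) {
    vals <- unlist(lapply(per_copy, function(p) p[ch]))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      # e.g. Y with an all-XX reference set: no per-copy information at all
      warning("no informative reference for chromosome ", ch,
              "; omitted from the reference statistics", call. = FALSE)
      return(NULL)
    }
    if (length(vals) < 2) {
      stop("fewer than 2 informative references for chromosome ", ch,
           call. = FALSE)
    }
    data.frame(chromosome = ch, per_copy_mean = mean(vals),
               per_copy_sd = stats::sd(vals), n_ref = length(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats_rows)
  if (any(out$per_copy_sd == 0)) {
    stop("zero coverage-ratio SD for chromosome(s) ",
         paste(out$chromosome[out$per_copy_sd == 0], collapse = ", "),
         "; add reference genomes or inject depth jitter", call. = FALSE)
  }
  if (any(out$per_copy_mean <= 0)) {
    stop("non-positive per-copy mean ratio in references", call. = FALSE)
  }
  class(out) <- c("reference_stats", "data.frame")
  out
}

# Round a per-copy estimate with deterministic tie handling: exact .5 ties
# resolve toward `toward` (expected copies for autosomes, the smaller copy
# number for gonosomes).
round_copies <- function(raw, toward) {
  lo <- floor(raw)
  hi <- lo + 1
  tie <- (raw - lo) == 0.5
  out <- round(raw)          # note round() is banker's; overwrite ties below
  out[tie] <- ifelse(abs(lo[tie] - toward[tie]) <= abs(hi[tie] - toward[tie]),
                     lo[tie], hi[tie])
  pmax(out, 0)
}

#' Estimate per-chromosome copy number for one sample
#'
#' Each chromosome's ratio is converted to copies by dividing by the
#' reference per-copy mean and rounding; the z-score measures the ratio's
#' deviation from the expectation for a karyotypically normal genome
#' (2 copies for autosomes) in units of the reference SD at that copy
#' number. Autosomes are flagged as putative aneuploidies when the rounded
#' copy number differs from 2 and |z| exceeds \code{z_threshold}. Gonosomal
#' copy numbers are never flagged here; they are interpreted by
#' \code{\link{call_karyotype}}.
#'
#' @param depth sample \code{\link{depth_table}}.
#' @param refs \code{reference_stats} from \code{\link{build_reference_stats}}.
#' @param z_threshold flag threshold on |z| (default 3).
#' @return data.frame of ploidy calls: \code{sample}, \code{chromosome},
#'   \code{ratio}, \code{z}, \code{copies}, \code{flagged}, plus \code{reads}
#'   carried through for downstream read-support checks.
#' @export
estimate_ploidy <- function(depth, refs, z_threshold = 3) {
  stopifnot(inherits(depth, "depth_table"))
  ratio <- normalize_depth(depth)
  missing_ref <- setdiff(names(ratio), refs$chromosome)
  if (length(missing_ref) > 0) {
    stop("no reference statistics for chromosome(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  idx <- match(names(ratio), refs$chromosome)
  pcm <- refs$per_copy_mean[idx]
  pcs <- refs$per_copy_sd[idx]
  auto <- names(ratio) %in% AUTOSOMES

  raw <- ratio / pcm
  toward <- ifelse(auto, 2, 0)   # gonosomal ties resolve conservatively down
  copies <- round_copies(raw, toward)

  # z against the normal-genome expectation for autosomes; against the
  # estimated copy number for gonosomes (whose normal state is sex-dependent)
  exp_copies <- ifelse(auto, 2, copies)
  z <- (ratio - exp_copies * pcm) / (pmax(exp_copies, 1) * pcs)

  flagged <- auto & copies != 2 & abs(z) > z_threshold
  out <- data.frame(sample = attr(depth, "sample"),
                    chromosome = names(ratio), ratio = as.numeric(ratio),
                    z = as.numeric(z), copies = as.integer(copies),
                    flagged = flagged,
                    reads = depth$reads[match(names(ratio),
                                              depth$chromosome)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ploidy_calls", "data.frame")
  out
}

#' Assemble a karyotype call from per-chromosome ploidy calls
#'
#' The gonosomal genotype string is \code{"X" * copies_X + "Y" * copies_Y}
#' (\code{X0} for a single X with no Y). Genetic sex is male iff at least
#' one Y copy is present and female iff the gonosomal genotype is XX or XXX;
#' anything else (including X0) is reported undetermined. When the combined
#' X+Y read count is below \code{min_reads} the call is undetermined rather
#' than wrong.
#'
#' @param calls ploidy calls from \code{\link{estimate_ploidy}}; must
#'   include X and Y.
#' @param min_reads minimum combined gonosomal read count (default 100).
#' @return a \code{karyotype_call} list: \code{sample}, \code{gonosomal},
#'   \code{genetic_sex}, \code{autosomal_trisomies},
#'   \code{autosomal_monosomies}, \code{min_informative}.
#' @export
call_karyotype <- function(calls, min_reads = 100) {
  known <- c("XX", "XY", "X0", "XXY", "XYY", "XXX")
  gx <- calls[calls$chromosome == "X", ]
  gy <- calls[calls$chromosome == "Y", ]
  tri <- calls$chromosome[calls$flagged & calls$copies > 2]
  mono <- calls$chromosome[calls$flagged & calls$copies < 2]
  res <- list(sample = calls$sample[1], gonosomal = "undetermined",
              genetic_sex = "undetermined",
              autosomal_trisomies = tri, autosomal_monosomies = mono,
              min_informative = FALSE)
  if (nrow(gx) == 0 || nrow(gy) == 0) {
    class(res) <- "karyotype_call"
    return(res)
  }
  gono_reads <- gx$reads + gy$reads
  if (is.na(gono_reads) || gono_reads < min_reads) {
    class(res) <- "karyotype_call"
    return(res)
  }
  res$min_informative <- TRUE
  nx <- gx$copies
  ny <- gy$copies
  gono <- if (nx == 1 && ny == 0) "X0" else {
    paste0(strrep("X", nx), strrep("Y", ny))
  }
  if (!gono %in% known) gono <- "undetermined"
  res$gonosomal <- gono
  res$genetic_sex <- if (gono == "undetermined") "undetermined"
    else if (ny >= 1) "M"
    else if (gono %in% c("XX", "XXX")) "F"
    else "undetermined"
  class(res) <- "karyotype_call"
  res
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat(sprintf("karyotype_call: %s  gonosomal=%s  sex=%s%s\n", x$sample,
              x$gonosomal, x$genetic_sex,
              if (!x$min_informative) "  (insufficient gonosomal reads)"
              else ""))
  if (length(x$autosomal_trisomies) > 0)
    cat("  trisomies:", paste(x$autosomal_trisomies, collapse = ", "), "\n")
  if (length(x$autosomal_monosomies) > 0)
    cat("  monosomies:", paste(x$autosomal_monosomies, collapse = ", "), "\n")
  invisible(x)
}
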