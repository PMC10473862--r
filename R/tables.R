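# TSV dialects: variant panels, pileup evidence, per-chromosome depth tables.
# All tab-separated with a header row, UTF-8, no quoting; coordinates 1-based.

#' Read a variant panel definition
#'
#' Panels are TSVs with columns \code{rsID}, \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{significance}, \code{condition}. The
#' mutation class (transition vs transversion) is computed from the alleles,
#' never read from the file. Entries are returned sorted by
#' (chromosome, position).
#'
#' @param path panel TSV.
#' @return data.frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position}, \code{ref}, \code{alt}, \code{mutation_class},
#'   \code{significance}, \code{condition}.
#' @export
read_panel <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  need <- c("rsID", "chrom", "pos", "ref", "alt", "significance", "condition")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  panel <- data.frame(
    snp_id = raw$rsID,
    chromosome = normalize_chromosome(raw$chrom),
    position = as.integer(raw$pos),
    ref = toupper(raw$ref), alt = toupper(raw$alt),
    significance = raw$significance, condition = raw$condition,
    stringsAsFactors = FALSE
  )
  if (nrow(panel) > 0) {
    check_alleles(panel$ref, panel$alt)
    if (any(!nzchar(panel$significance))) {
      stop("panel significance must be non-empty", call. = FALSE)
    }
    key <- paste(panel$chromosome, panel$position)
    if (anyDuplicated(key)) {
      stop("duplicate panel site: ", key[duplicated(key)][1], call. = FALSE)
    }
    panel$mutation_class <- mutation_class(panel$ref, panel$alt)
    panel <- panel[order(chromosome_rank(panel$chromosome), panel$position), ]
    rownames(panel) <- NULL
  } else {
    panel$mutation_class <- character(0)
  }
  panel[, c("snp_id", "chromosome", "position", "ref", "alt",
            "mutation_class", "significance", "condition")]
}

#' Write a variant panel definition
#'
#' @param panel data.frame as returned by \code{\link{read_panel}} (the
#'   \code{mutation_class} column, if present, is dropped: it is derived).
#' @param path output TSV.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(rsID = panel$snp_id, chrom = panel$chromosome,
                    pos = panel$position, ref = panel$ref, alt = panel$alt,
                    significance = panel$significance,
                    condition = panel$condition, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-site pileup evidence
#'
#' TSV with columns \code{sample}, \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{depth}, \code{alt_depth}. Each record's invariants are
#' enforced: \code{0 <= alt_depth <= depth}. A record with depth 0 is valid
#' (it yields a no-call downstream).
#'
#' @param path pileup TSV.
#' @return data.frame of pileup records with normalized chromosomes.
#' @export
read_pileup <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("sample", "chrom", "pos", "ref", "alt", "depth", "alt_depth")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("pileup lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pu <- data.frame(
    sample = as.character(raw$sample),
    chromosome = normalize_chromosome(raw$chrom),
    position = as.integer(raw$pos),
    ref = toupper(as.character(raw$ref)), alt = toupper(as.character(raw$alt)),
    depth = as.integer(raw$depth), alt_depth = as.integer(raw$alt_depth),
    stringsAsFactors = FALSE
  )
  validate_pileup(pu)
  pu
}

validate_pileup <- function(pu) {
  if (nrow(pu) == 0) return(invisible(pu))
  check_alleles(pu$ref, pu$alt)
  if (any(pu$depth < 0)) {
    stop("pileup depth must be >= 0 (line ", which(pu$depth < 0)[1] + 1, ")",
         call. = FALSE)
  }
  bad <- pu$alt_depth > pu$depth | pu$alt_depth < 0
  if (any(bad)) {
    stop("pileup alt_depth exceeds depth (line ", which(bad)[1] + 1, ")",
         call. = FALSE)
  }
  invisible(pu)
}

#' Write per-site pileup evidence
#' @param pu pileup data.frame (see \code{\link{read_pileup}}).
#' @param path output TSV.
#' @export
write_pileup <- function(pu, path) {
  out <- data.frame(sample = pu$sample, chrom = pu$chromosome,
                    pos = pu$position, ref = pu$ref, alt = pu$alt,
                    depth = pu$depth, alt_depth = pu$alt_depth,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-chromosome depth tables
#'
#' TSV with columns \code{sample}, \code{chrom}, \code{reads}, \code{sites}:
#' read counts over a fixed SNP panel, per chromosome. Possibly several
#' samples per file.
#'
#' @param path depth TSV.
#' @return named list of \code{\link{depth_table}} objects, one per sample.
#' @export
read_depth_tables <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("sample", "chrom", "reads", "sites")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("depth table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  split_rows <- split(raw, raw$sample)
  out <- lapply(split_rows, function(d) {
    depth_table(sample = d$sample[1],
                chrom = d$chrom, reads = d$reads, sites = d$sites)
  })
  out[unique(raw$sample)]
}

#' Write per-chromosome depth tables
#' @param tables a \code{depth_table} or list of them.
#' @param path output TSV.
#' @export
write_depth_tables <- function(tables, path) {
  if (inherits(tables, "depth_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(d) {
    data.frame(sample = attr(d, "sample"), chrom = d$chromosome,
               reads = d$reads, sites = d$sites, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read declared reference karyotypes
#'
#' TSV with columns \code{sample}, \code{karyotype} (XX or XY), used to
#' declare reference genomes karyotypically normal when building reference
#' coverage statistics.
#'
#' @param path TSV path.
#' @return named character vector sample -> karyotype.
#' @export
read_karyotypes <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample", "karyotype") %in% names(raw))) {
    stop("karyotype table needs columns sample, karyotype", call. = FALSE)
  }
  stats::setNames(as.character(raw$karyotype), as.character(raw$sample))
}
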