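# EIGENSTRAT .geno/.snp/.ind input/output and the pseudohaploid matrix
# container. Genotypes follow EIGENSTRAT reference-allele-count semantics:
# 2 = two ref doses, 0 = zero ref doses (i.e. alt), 9 = missing. Pseudohaploid
# matrices never contain 1 (a single sampled allele is encoded homozygous).

#' Construct a pseudohaploid genotype matrix
#'
#' @param calls integer matrix, samples in rows, SNPs in columns, values in
#'   \{0, 2, 9\} (\{0, 1, 2, 9\} with \code{diploid = TRUE}).
#' @param snps data.frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position}, \code{ref}, \code{alt}; one row per matrix column.
#' @param samples sample identifiers; defaults to \code{rownames(calls)}.
#' @param diploid allow heterozygous value 1 (used for simulator truth
#'   tables before pseudohaploidization).
#' @return object of class \code{pseudohaploid_matrix}: a list with elements
#'   \code{samples}, \code{snps}, \code{calls} (dimnamed matrix) and the
#'   \code{diploid} policy flag.
#' @export
pseudohaploid_matrix <- function(calls, snps, samples = rownames(calls),
                                 diploid = FALSE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) stop("sample identifiers are required", call. = FALSE)
  samples <- as.character(samples)
  snps <- validate_snp_table(snps)
  if (nrow(calls) != length(samples)) {
    stop(sprintf("calls has %d rows but %d sample ids given",
                 nrow(calls), length(samples)), call. = FALSE)
  }
  if (ncol(calls) != nrow(snps)) {
    stop(sprintf("calls has %d columns but %d SNP records given",
                 ncol(calls), nrow(snps)), call. = FALSE)
  }
  allowed <- if (diploid) c(0L, 1L, 2L, 9L) else c(0L, 2L, 9L)
  if (nrow(calls) > 0 && !all(calls %in% allowed)) {
    stop("genotype values outside {", paste(allowed, collapse = ","),
         "}; pseudohaploid matrices may not contain heterozygous calls (1)",
         call. = FALSE)
  }
  dimnames(calls) <- list(samples, snps$snp_id)
  structure(list(samples = samples, snps = snps, calls = calls,
                 diploid = diploid),
            class = "pseudohaploid_matrix")
}

validate_snp_table <- function(snps) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chromosome", "position", "ref", "alt")
  missing_cols <- setdiff(need, names(snps))
  if (length(missing_cols) > 0) {
    stop("snp table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- normalize_chromosome(snps$chromosome)
  snps$position <- as.integer(snps$position)
  if (any(snps$position < 1)) {
    stop("positions are 1-based and must be >= 1", call. = FALSE)
  }
  if (nrow(snps) > 0) check_alleles(snps$ref, snps$alt)
  key <- paste(snps$chromosome, snps$position)
  if (anyDuplicated(key)) {
    stop("duplicate (chromosome, position) in SNP table: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  snps[, need]
}

#' @export
print.pseudohaploid_matrix <- function(x, ...) {
  cat(sprintf("pseudohaploid_matrix: %d samples x %d SNPs (%s)\n",
              length(x$samples), nrow(x$snps),
              if (x$diploid) "diploid policy" else "pseudohaploid"))
  miss <- if (length(x$calls) > 0) mean(x$calls == 9L) else NA_real_
  cat(sprintf("  missingness: %s\n",
              if (is.na(miss)) "NA" else sprintf("%.1f%%", 100 * miss)))
  invisible(x)
}

#' Read an EIGENSTRAT genotype trio
#'
#' Reads \code{<prefix>.geno} (one row per SNP, one character per sample),
#' \code{<prefix>.snp} and \code{<prefix>.ind}. Under the default
#' pseudohaploid policy any heterozygous value 1 is recoded to missing (9)
#' with one warning; pass \code{diploid = TRUE} to keep heterozygotes (e.g.
#' for simulator truth output).
#'
#' @param prefix path stem of the trio.
#' @param diploid keep heterozygous calls instead of recoding them.
#' @return a \code{\link{pseudohaploid_matrix}}.
#' @export
read_eigenstrat <- function(prefix, diploid = FALSE) {
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (f in files) {
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  }
  geno_lines <- readLines(files[1])
  snp_raw <- read_ws_table(files[2])
  ind_raw <- read_ws_table(files[3])

  n_snp <- if (length(geno_lines) == 1 && !nzchar(geno_lines)) 0L
           else length(geno_lines)
  if (n_snp == 0L) geno_lines <- character(0)
  if (n_snp != nrow(snp_raw)) {
    stop(sprintf(".geno has %d rows but .snp has %d entries",
                 n_snp, nrow(snp_raw)), call. = FALSE)
  }
  n_ind <- nrow(ind_raw)
  widths <- nchar(geno_lines)
  if (any(widths != n_ind)) {
    stop(sprintf(".geno has %d columns (line %d) but .ind has %d entries",
                 widths[which(widths != n_ind)[1]],
                 which(widths != n_ind)[1], n_ind), call. = FALSE)
  }

  # .snp columns: id, chrom, genetic pos, physical pos, ref, alt
  if (n_snp > 0 && ncol(snp_raw) < 6) {
    stop(".snp must have 6 columns (id chrom gpos pos ref alt)",
         call. = FALSE)
  }
  snps <- if (n_snp > 0) {
    data.frame(snp_id = snp_raw[[1]], chromosome = snp_raw[[2]],
               position = as.integer(snp_raw[[4]]),
               ref = snp_raw[[5]], alt = snp_raw[[6]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(0), chromosome = character(0),
               position = integer(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
  }

  calls <- matrix(9L, nrow = n_ind, ncol = n_snp)
  if (n_snp > 0 && n_ind > 0) {
    chars <- strsplit(geno_lines, "", fixed = TRUE)
    bad <- !vapply(chars, function(x) all(x %in% c("0", "1", "2", "9")),
                   logical(1))
    if (any(bad)) {
      stop(".geno contains characters outside {0,1,2,9} at line ",
           which(bad)[1], call. = FALSE)
    }
    # vapply over SNP lines: each line holds one character per sample, so
    # the result is already samples x snps
    calls <- vapply(chars, function(x) as.integer(x), integer(n_ind))
    dim(calls) <- c(n_ind, n_snp)
    if (!diploid && any(calls == 1L)) {
      n1 <- sum(calls == 1L)
      warning(sprintf(
        "%d heterozygous call(s) recoded to missing under pseudohaploid policy",
        n1), call. = FALSE)
      calls[calls == 1L] <- 9L
    }
  }
  samples <- if (n_ind > 0) as.character(ind_raw[[1]]) else character(0)
  pseudohaploid_matrix(calls, snps, samples = samples, diploid = diploid)
}

read_ws_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(data.frame())
  parts <- strsplit(trimws(lines), "[ \t]+")
  ncols <- max(lengths(parts))
  cols <- lapply(seq_len(ncols), function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_,
           character(1))
  })
  as.data.frame(cols, col.names = paste0("V", seq_len(ncols)),
                stringsAsFactors = FALSE)
}

#' Write an EIGENSTRAT genotype trio
#'
#' Inverse of \code{\link{read_eigenstrat}}; the round trip is bit-exact.
#' Matrices containing heterozygous value 1 are refused unless they carry
#' the diploid policy flag.
#'
#' @param x a \code{\link{pseudohaploid_matrix}}.
#' @param prefix output path stem.
#' @return \code{prefix}, invisibly.
#' @export
write_eigenstrat <- function(x, prefix) {
  stopifnot(inherits(x, "pseudohaploid_matrix"))
  if (!x$diploid && any(x$calls == 1L)) {
    stop("matrix contains heterozygous calls but lacks the diploid policy; ",
         "refusing to write as pseudohaploid", call. = FALSE)
  }
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  n_snp <- nrow(x$snps)
  geno <- if (n_snp > 0 && length(x$samples) > 0) {
    apply(x$calls, 2, paste, collapse = "")
  } else if (n_snp > 0) {
    rep("", n_snp)
  } else {
    character(0)
  }
  writeLines(geno, paste0(prefix, ".geno"))
  snp_lines <- if (n_snp > 0) {
    sprintf("%s\t%s\t%.6f\t%d\t%s\t%s", x$snps$snp_id, x$snps$chromosome,
            0, x$snps$position, x$snps$ref, x$snps$alt)
  } else character(0)
  writeLines(snp_lines, paste0(prefix, ".snp"))
  ind_lines <- if (length(x$samples) > 0) {
    sprintf("%s\tU\tCohort", x$samples)
  } else character(0)
  writeLines(ind_lines, paste0(prefix, ".ind"))
  invisible(prefix)
}
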