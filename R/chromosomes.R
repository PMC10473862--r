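# Chromosome naming conventions and GRCh37 metrics shared by all modules.

# GRCh37.p13 chromosome lengths (bp); basis for length-proportional SNP maps
# and for 20 Mb jackknife blocks.
GRCH37_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566,
  "MT" = 16569
)

AUTOSOMES <- as.character(1:22)
GONOSOMES <- c("X", "Y")
CHROMOSOMES <- c(AUTOSOMES, GONOSOMES, "MT")

#' Normalize chromosome labels
#'
#' Strips any leading \code{"chr"} prefix and maps the mitochondrial aliases
#' \code{"M"}, \code{"MT"}, \code{"chrM"} to \code{"MT"}. Labels outside
#' \{1..22, X, Y, MT\} raise an error.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' normalize_chromosome(c("chr1", "X", "chrM", "MT"))
normalize_chromosome <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  chrom[chrom == "M"] <- "MT"
  bad <- setdiff(unique(chrom), CHROMOSOMES)
  if (length(bad) > 0) {
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  chrom
}

#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) substitutions are
#' transitions; all other ref/alt pairs are transversions. The classification
#' is strand-symmetric: complement-swapped pairs (e.g. A>G vs T>C) receive
#' the same class. Transitions matter downstream because post-mortem
#' cytosine deamination produces spurious C>T / G>A calls.
#'
#' @param ref,alt allele characters in \{A, C, G, T\}; \code{ref != alt}.
#' @return character vector, \code{"transition"} or \code{"transversion"}.
#' @export
#' @examples
#' mutation_class("A", "G")  # transition
#' mutation_class("A", "T")  # transversion
mutation_class <- function(ref, alt) {
  check_alleles(ref, alt)
  purine <- c("A", "G")
  same_class <- (ref %in% purine) == (alt %in% purine)
  ifelse(same_class, "transition", "transversion")
}

check_alleles <- function(ref, alt) {
  ok <- c("A", "C", "G", "T")
  if (!all(ref %in% ok) || !all(alt %in% ok)) {
    stop("alleles must be one of A, C, G, T", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  invisible(TRUE)
}

# Order rows by (chromosome, position) with chromosomes in karyotype order.
chromosome_rank <- function(chrom) {
  match(chrom, CHROMOSOMES)
}

#' Per-chromosome site counts for a 1240k-like capture panel
#'
#' Distributes a total number of panel sites over chromosomes 1-22, X and Y
#' proportionally to GRCh37 chromosome length. This emulates the density of
#' the ~1.24M-site capture arrays standard in ancient-genome genotyping and
#' is the default substrate for depth simulation and ploidy estimation.
#'
#' @param total_sites total panel size (default 1,150,000).
#' @param chromosomes chromosome subset (default autosomes + X + Y).
#' @return named integer vector of site counts per chromosome.
#' @export
default_site_map <- function(total_sites = 1150000,
                             chromosomes = c(AUTOSOMES, GONOSOMES)) {
  chromosomes <- normalize_chromosome(chromosomes)
  len <- GRCH37_LENGTHS[chromosomes]
  sites <- round(total_sites * len / sum(len))
  sites[sites < 1] <- 1
  storage.mode(sites) <- "integer"
  sites
}
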