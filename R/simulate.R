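# Synthetic ancient-DNA data: pedigree gene dropping for genotypes,
# Bernoulli single-read pseudohaploidization with deamination damage,
# Poisson per-chromosome depth tables per karyotype, and damaged pileups.
#
# Sites are independent (no linkage/recombination): identity-by-descent is
# site-wise i.i.d., which is sufficient for mismatch-rate and coverage-ratio
# expectations but rules out IBD-segment methods (out of scope here).

#' Simulation configuration
#'
#' @param n_sites number of SNP sites.
#' @param freq_range range of the uniform alt-allele frequency sampler.
#' @param coverage mean per-site coverage in x units. For genotype
#'   pseudohaploidization this is the Bernoulli probability a site carries a
#'   read (capped at 1), matching the shotgun regime where covered sites
#'   mostly hold a single read; for depth/pileup simulation it is the
#'   Poisson mean.
#' @param damage_rate probability a sampled C (G) is read as T (A),
#'   emulating residual post-mortem deamination in half-UDG libraries.
#' @param error_rate per-call probability of a random allele flip.
#' @param seed integer RNG seed.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_sites = 50000, freq_range = c(0.05, 0.95),
                       coverage = 1.0, damage_rate = 0, error_rate = 0,
                       seed = 1L) {
  stopifnot(n_sites >= 1, coverage > 0,
            damage_rate >= 0, damage_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            length(freq_range) == 2, freq_range[1] <= freq_range[2],
            freq_range[1] >= 0, freq_range[2] <= 1)
  structure(list(n_sites = as.integer(n_sites), freq_range = freq_range,
                 coverage = coverage, damage_rate = damage_rate,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Pedigree specification
#'
#' @param founders character vector of founder ids.
#' @param matings data.frame (parent_a, parent_b, child); children may
#'   themselves parent later matings. Dizygotic twins are two children of
#'   the same mating.
#' @param duplicates data.frame (source, copy): same-individual replicates
#'   (e.g. two libraries from one skeleton, or monozygotic twins).
#' @return a \code{pedigree_spec} list.
#' @export
pedigree_spec <- function(founders, matings = NULL, duplicates = NULL) {
  founders <- as.character(founders)
  if (anyDuplicated(founders)) stop("duplicate founder ids", call. = FALSE)
  if (is.null(matings)) {
    matings <- data.frame(parent_a = character(0), parent_b = character(0),
                          child = character(0), stringsAsFactors = FALSE)
  }
  matings <- as.data.frame(matings, stringsAsFactors = FALSE)
  names(matings) <- c("parent_a", "parent_b", "child")
  if (is.null(duplicates)) {
    duplicates <- data.frame(source = character(0), copy = character(0),
                             stringsAsFactors = FALSE)
  }
  duplicates <- as.data.frame(duplicates, stringsAsFactors = FALSE)
  names(duplicates) <- c("source", "copy")

  known <- founders
  for (i in seq_len(nrow(matings))) {
    pa <- matings$parent_a[i]; pb <- matings$parent_b[i]
    ch <- matings$child[i]
    if (!pa %in% known || !pb %in% known) {
      stop("mating ", i, ": parent defined after child or unknown (",
           pa, " x ", pb, "); pedigree must be acyclic and ordered",
           call. = FALSE)
    }
    if (ch %in% known) stop("individual defined twice: ", ch, call. = FALSE)
    known <- c(known, ch)
  }
  for (i in seq_len(nrow(duplicates))) {
    if (!duplicates$source[i] %in% known) {
      stop("duplicate source unknown: ", duplicates$source[i], call. = FALSE)
    }
    if (duplicates$copy[i] %in% known) {
      stop("individual defined twice: ", duplicates$copy[i], call. = FALSE)
    }
    known <- c(known, duplicates$copy[i])
  }
  structure(list(founders = founders, matings = matings,
                 duplicates = duplicates, individuals = known),
            class = "pedigree_spec")
}

#' Expected kinship coefficients implied by a pedigree
#'
#' Standard recursive kinship computation (phi of an individual with itself
#' is 1/2 absent inbreeding; phi(child, x) averages the parents' phi with
#' x). Duplicates share their source's genome, so phi(copy, source) = 1/2.
#'
#' @param ped a \code{\link{pedigree_spec}}.
#' @return symmetric matrix of kinship coefficients.
#' @export
kinship_coefficients <- function(ped) {
  ids <- ped$individuals
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  parents <- list()
  for (f in ped$founders) parents[[f]] <- NULL
  for (i in seq_len(nrow(ped$matings))) {
    parents[[ped$matings$child[i]]] <-
      c(ped$matings$parent_a[i], ped$matings$parent_b[i])
  }
  dup_src <- stats::setNames(ped$duplicates$source, ped$duplicates$copy)
  # individuals are listed parents-before-children, so one forward pass works
  for (i in seq_len(n)) {
    a <- ids[i]
    src_a <- if (a %in% names(dup_src)) dup_src[[a]] else a
    pa <- parents[[src_a]]
    for (j in seq_len(i)) {
      b <- ids[j]
      src_b <- if (b %in% names(dup_src)) dup_src[[b]] else b
      if (identical(src_a, src_b)) {
        phi[a, b] <- phi[b, a] <- 0.5
      } else if (match(src_a, ids) < match(src_b, ids)) {
        # recurse through the later-defined individual's parents
        pb <- parents[[src_b]]
        v <- if (is.null(pb)) 0 else mean(phi[src_a, pb])
        phi[a, b] <- phi[b, a] <- v
      } else {
        v <- if (is.null(pa)) 0 else mean(phi[src_b, pa])
        phi[a, b] <- phi[b, a] <- v
      }
    }
  }
  phi
}

# Draw a site map: chromosomes sampled proportionally to length over the
# autosomes, positions uniform, ref/alt drawn over ordered base pairs (so a
# third of sites are transitions on average).
simulate_snp_map <- function(n_sites, chromosomes = AUTOSOMES) {
  len <- GRCH37_LENGTHS[chromosomes]
  chrom <- sample(chromosomes, n_sites, replace = TRUE, prob = len)
  pos <- floor(stats::runif(n_sites, 1, len[chrom])) + 0
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  map <- data.frame(snp_id = sprintf("snp%06d", seq_len(n_sites)),
                    chromosome = chrom, position = as.integer(pos),
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  map <- map[order(chromosome_rank(map$chromosome), map$position), ]
  # de-duplicate the rare coordinate collision by shifting one bp
  key <- paste(map$chromosome, map$position)
  while (anyDuplicated(key)) {
    d <- duplicated(key)
    map$position[d] <- map$position[d] + 1L
    map <- map[order(chromosome_rank(map$chromosome), map$position), ]
    key <- paste(map$chromosome, map$position)
  }
  rownames(map) <- NULL
  map$snp_id <- sprintf("snp%06d", seq_len(nrow(map)))
  map
}

#' Gene-drop diploid genotypes through a pedigree
#'
#' Founders are drawn site-wise from Hardy-Weinberg proportions at an
#' alt-allele frequency sampled per site from the configured uniform range;
#' each child inherits one uniformly chosen allele per parent per site;
#' duplicates copy their source's genome. Reproducible under the config
#' seed.
#'
#' @param ped a \code{\link{pedigree_spec}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{snps} (site map), \code{haplotypes} (two
#'   0/1 alt-dose matrices \code{h1}, \code{h2}, individuals x sites),
#'   \code{geno} (ref-dose diploid matrix, values 0/1/2) and \code{freq}
#'   (per-site alt frequency).
#' @export
simulate_pedigree_genotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree_spec"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sites
  snps <- simulate_snp_map(n)
  freq <- stats::runif(n, cfg$freq_range[1], cfg$freq_range[2])
  ids <- ped$individuals
  h1 <- matrix(0L, length(ids), n, dimnames = list(ids, NULL))
  h2 <- h1
  for (f in ped$founders) {
    h1[f, ] <- stats::rbinom(n, 1, freq)
    h2[f, ] <- stats::rbinom(n, 1, freq)
  }
  for (i in seq_len(nrow(ped$matings))) {
    pa <- ped$matings$parent_a[i]; pb <- ped$matings$parent_b[i]
    ch <- ped$matings$child[i]
    pick_a <- stats::rbinom(n, 1, 0.5) == 1
    pick_b <- stats::rbinom(n, 1, 0.5) == 1
    h1[ch, ] <- ifelse(pick_a, h1[pa, ], h2[pa, ])
    h2[ch, ] <- ifelse(pick_b, h1[pb, ], h2[pb, ])
  }
  for (i in seq_len(nrow(ped$duplicates))) {
    src <- ped$duplicates$source[i]; cp <- ped$duplicates$copy[i]
    h1[cp, ] <- h1[src, ]
    h2[cp, ] <- h2[src, ]
  }
  geno <- 2L - (h1 + h2)   # ref-dose: 2 = hom ref, 0 = hom alt
  list(snps = snps, haplotypes = list(h1 = h1, h2 = h2),
       geno = geno, freq = freq)
}

#' Pseudohaploidize diploid genotypes
#'
#' Per sample and site: the site is covered with probability
#' \code{min(coverage, 1)}; if covered one of the two alleles is sampled
#' uniformly; deamination damage turns a sampled C into T and a sampled G
#' into A with probability \code{damage_rate}; with probability
#' \code{error_rate} the observed allele flips to the other panel allele.
#' The observed base is encoded against the site's ref/alt labels
#' (2 = ref, 0 = alt); a damaged base matching neither label is recorded
#' missing.
#'
#' @param sim output of \code{\link{simulate_pedigree_genotypes}}.
#' @param cfg a \code{\link{sim_config}}; its \code{seed} is offset from the
#'   gene-dropping seed so genotypes and read sampling are independent.
#' @return a \code{\link{pseudohaploid_matrix}}.
#' @export
pseudohaploidize <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1000003L)
  h1 <- sim$haplotypes$h1
  h2 <- sim$haplotypes$h2
  n_ind <- nrow(h1); n <- ncol(h1)
  ref <- sim$snps$ref; alt <- sim$snps$alt
  p_cov <- min(cfg$coverage, 1)
  calls <- matrix(9L, n_ind, n)
  for (i in seq_len(n_ind)) {
    covered <- stats::runif(n) < p_cov
    pick1 <- stats::runif(n) < 0.5
    allele <- ifelse(pick1, h1[i, ], h2[i, ])        # 0 = ref, 1 = alt
    base <- ifelse(allele == 1L, alt, ref)
    if (cfg$damage_rate > 0) {
      dmg <- stats::runif(n) < cfg$damage_rate
      base[dmg & base == "C"] <- "T"
      base[dmg & base == "G"] <- "A"
    }
    call <- ifelse(base == ref, 2L, ifelse(base == alt, 0L, 9L))
    if (cfg$error_rate > 0) {
      err <- stats::runif(n) < cfg$error_rate & call != 9L
      call[err] <- 2L - call[err]
    }
    call[!covered] <- 9L
    calls[i, ] <- call
  }
  pseudohaploid_matrix(calls, sim$snps, samples = rownames(h1))
}

#' Simulate a per-chromosome depth table for a karyotype
#'
#' Read counts per chromosome are Poisson with mean
#' \code{sites_c * coverage * copies_c / 2}, so a disomic chromosome at
#' coverage x carries x reads per site on average.
#'
#' @param karyotype karyotype string (see \code{\link{parse_karyotype}}).
#' @param sites_per_chromosome named site counts (default a 1240k-like map,
#'   \code{\link{default_site_map}}).
#' @param coverage mean autosomal coverage in x units.
#' @param seed integer seed.
#' @param sample sample identifier.
#' @return a \code{\link{depth_table}}.
#' @export
simulate_depth_table <- function(karyotype,
                                 sites_per_chromosome = default_site_map(),
                                 coverage = 0.05, seed = 1L,
                                 sample = karyotype) {
  copies <- parse_karyotype(karyotype)
  chroms <- names(sites_per_chromosome)
  set.seed(as.integer(seed))
  lambda <- sites_per_chromosome * coverage * copies[chroms] / 2
  reads <- stats::rpois(length(chroms), lambda)
  depth_table(sample = sample, chrom = chroms, reads = reads,
              sites = sites_per_chromosome)
}

#' Simulate pileup evidence over a variant panel
#'
#' Per sample and panel site: total depth is Poisson(\code{coverage}); each
#' read samples one of the individual's two alleles, deamination and error
#' are applied per read as in \code{\link{pseudohaploidize}}, and
#' \code{alt_depth} counts reads whose observed base equals the panel alt.
#' Reads whose observed base matches neither panel allele reduce neither
#' count but still count toward \code{depth}.
#'
#' @param panel panel data.frame (see \code{\link{read_panel}}).
#' @param genotypes named list sample -> integer vector of alt-allele doses
#'   (0, 1 or 2) per panel site, in panel order.
#' @param coverage mean read depth at panel sites.
#' @param cfg a \code{\link{sim_config}} supplying damage_rate, error_rate,
#'   seed.
#' @return pileup data.frame (see \code{\link{read_pileup}}).
#' @export
simulate_pileup <- function(panel, genotypes, coverage, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2000003L)
  n <- nrow(panel)
  rows <- lapply(names(genotypes), function(s) {
    dose <- genotypes[[s]]
    stopifnot(length(dose) == n)
    depth <- stats::rpois(n, coverage)
    alt_depth <- integer(n)
    for (i in which(depth > 0)) {
      alt_allele <- stats::rbinom(depth[i], 1, dose[i] / 2) == 1
      base <- ifelse(alt_allele, panel$alt[i], panel$ref[i])
      if (cfg$damage_rate > 0) {
        dmg <- stats::runif(depth[i]) < cfg$damage_rate
        base[dmg & base == "C"] <- "T"
        base[dmg & base == "G"] <- "A"
      }
      if (cfg$error_rate > 0) {
        err <- stats::runif(depth[i]) < cfg$error_rate
        flip <- err & base %in% c(panel$ref[i], panel$alt[i])
        base[flip] <- ifelse(base[flip] == panel$ref[i],
                             panel$alt[i], panel$ref[i])
      }
      alt_depth[i] <- sum(base == panel$alt[i])
    }
    data.frame(sample = s, chromosome = panel$chromosome,
               position = panel$position, ref = panel$ref, alt = panel$alt,
               depth = depth, alt_depth = alt_depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
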