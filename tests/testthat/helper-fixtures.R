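# Shared fixture builders; everything is generated in code.

tiny_snp_table <- function(n = 4, chrom = "1", spacing = 1e6) {
  data.frame(snp_id = sprintf("s%d", seq_len(n)),
             chromosome = rep(chrom, length.out = n),
             position = as.integer(seq_len(n) * spacing),
             ref = rep(c("A", "C", "G", "T"), length.out = n),
             alt = rep(c("G", "T", "A", "C"), length.out = n),
             stringsAsFactors = FALSE)
}

tiny_matrix <- function(calls, snps = NULL, samples = NULL, ...) {
  calls <- as.matrix(calls)
  if (is.null(snps)) snps <- tiny_snp_table(ncol(calls))
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(calls)))
  pseudohaploid_matrix(calls, snps, samples = samples, ...)
}

# noiseless depth table: reads = sites * rate * copies/2 exactly
exact_depth <- function(sample = "s", rate = 0.05,
                        copies = c(stats::setNames(rep(2, 22), as.character(1:22)),
                                   X = 2, Y = 0),
                        sites = NULL) {
  chroms <- names(copies)
  if (is.null(sites)) sites <- stats::setNames(rep(10000, length(chroms)), chroms)
  depth_table(sample = sample, chrom = chroms,
              reads = sites[chroms] * rate * copies / 2, sites = sites[chroms])
}

# handcrafted per-copy reference stats (exact means, small positive sd)
exact_reference_stats <- function(chroms = c(as.character(1:22), "X", "Y"),
                                  per_copy_mean = 0.5, per_copy_sd = 0.01) {
  out <- data.frame(chromosome = chroms,
                    per_copy_mean = per_copy_mean,
                    per_copy_sd = per_copy_sd,
                    n_ref = 10L, stringsAsFactors = FALSE)
  class(out) <- c("reference_stats", "data.frame")
  out
}

write_tsv_tmp <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "table.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

simulated_reference_set <- function(n_each = 10, site_map = default_site_map(),
                                    coverage = 0.1, seed = 900) {
  kts <- c(rep("XX", n_each), rep("XY", n_each))
  ids <- sprintf("ref%02d", seq_along(kts))
  refs <- lapply(seq_along(kts), function(i) {
    simulate_depth_table(kts[i], site_map, coverage = coverage,
                         seed = seed + i, sample = ids[i])
  })
  list(refs = refs, karyotypes = stats::setNames(kts, ids))
}
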