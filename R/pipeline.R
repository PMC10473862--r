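# Cohort-level aggregation and the end-to-end pipeline driver.

#' Aggregate genetic-sex calls per cohort group
#'
#' Counts males, females and undetermined calls per group label and reports
#' the male percentage as an integer percent, floored, over determinate
#' calls only. Use a shared label to pool groups.
#'
#' @param sexes data.frame with columns \code{sample}, \code{group},
#'   \code{sex} (values M, F or undetermined).
#' @return data.frame with one row per group: \code{group}, \code{n},
#'   \code{males}, \code{females}, \code{undetermined}, \code{male_pct}.
#' @export
#' @examples
#' aggregate_sex(data.frame(sample = c("a", "b", "c", "d"),
#'                          group = "g", sex = c("M", "M", "M", "F")))
aggregate_sex <- function(sexes) {
  need <- c("sample", "group", "sex")
  if (!all(need %in% names(sexes))) {
    stop("sex table needs columns sample, group, sex", call. = FALSE)
  }
  if (anyDuplicated(sexes$sample)) {
    stop("duplicate sample in sex table: ",
         sexes$sample[duplicated(sexes$sample)][1], call. = FALSE)
  }
  if (!all(sexes$sex %in% c("M", "F", "undetermined"))) {
    stop("sex must be M, F or undetermined", call. = FALSE)
  }
  rows <- lapply(split(sexes, sexes$group), function(g) {
    m <- sum(g$sex == "M"); f <- sum(g$sex == "F")
    data.frame(group = g$group[1], n = nrow(g), males = m, females = f,
               undetermined = sum(g$sex == "undetermined"),
               male_pct = if (m + f > 0) floor(100 * m / (m + f))
                          else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline from a declarative config
#'
#' Stages run in order: \code{simulate} (synthetic pedigree genotypes,
#' depth tables and pileups written through the standard formats),
#' \code{ploidy}, \code{kinship}, \code{screen}, \code{report}. Each stage
#' reads only files named in the config, so a rerun with the same config
#' and seed reproduces identical outputs. Stage parameters default to the
#' package defaults documented on the underlying functions.
#'
#' @param config named list (or path to a YAML/DCF-style file read with
#'   \code{yaml::read_yaml} if available) with elements \code{out_dir},
#'   \code{seed}, \code{stages} (character subset of
#'   simulate/ploidy/kinship/screen/report) and optional per-stage lists
#'   \code{simulate}, \code{ploidy}, \code{kinship}, \code{screen}.
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      stop("reading config files requires the yaml package; ",
           "pass a list instead", call. = FALSE)
    }
  }
  out_dir <- config[["out_dir"]] %||% stop("config$out_dir is required")
  seed <- as.integer(config[["seed"]] %||% 1L)
  stages <- config[["stages"]] %||% c("simulate", "ploidy", "kinship", "screen",
                                 "report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  unlink(log_path)

  # fail early on missing inputs for enabled non-simulate stages
  if (!"simulate" %in% stages) {
    need <- c(
      if ("ploidy" %in% stages) c(config[["ploidy"]]$depths, config[["ploidy"]]$refs,
                                  config[["ploidy"]]$ref_karyotypes),
      if ("kinship" %in% stages) paste0(config[["kinship"]]$geno_prefix,
                                        c(".geno", ".snp", ".ind")),
      if ("screen" %in% stages) c(config[["screen"]]$pileup, config[["screen"]]$panel)
    )
    missing_in <- need[!vapply(need, file.exists, logical(1))]
    if (length(missing_in) > 0) {
      stop("missing input(s) for enabled stage(s): ",
           paste(missing_in, collapse = ", "), call. = FALSE)
    }
  }

  if ("simulate" %in% stages) {
    sc <- config[["simulate"]] %||% list()
    cfg <- sim_config(n_sites = sc[["n_sites"]] %||% 20000,
                      coverage = sc[["coverage"]] %||% 0.7,
                      damage_rate = sc[["damage_rate"]] %||% 0.02,
                      seed = seed)
    ped <- if (!is.null(sc[["pedigree"]])) sc[["pedigree"]] else demo_pedigree()
    logf("simulate: %d sites, coverage %.3g, damage %.3g, seed %d",
         cfg$n_sites, cfg$coverage, cfg$damage_rate, seed)
    sim <- simulate_pedigree_genotypes(ped, cfg)
    mat <- pseudohaploidize(sim, cfg)
    paths$geno_prefix <- file.path(out_dir, "cohort")
    write_eigenstrat(mat, paths$geno_prefix)

    karyos <- sc[["karyotypes"]] %||%
      stats::setNames(rep(c("XY", "XX"), length.out = length(mat$samples)),
                      mat$samples)
    sm <- default_site_map(sc[["total_depth_sites"]] %||% 100000)
    depths <- lapply(names(karyos), function(s) {
      simulate_depth_table(karyos[[s]], sm,
                           coverage = sc[["depth_coverage"]] %||% 0.05,
                           seed = seed + match(s, names(karyos)),
                           sample = s)
    })
    paths$depths <- file.path(out_dir, "depths.tsv")
    write_depth_tables(depths, paths$depths)
    utils::write.table(
      data.frame(sample = names(karyos), karyotype = unname(karyos)),
      file.path(out_dir, "true_karyotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    panel <- if (!is.null(sc[["panel"]])) read_panel(sc[["panel"]]) else {
      read_panel(system.file("extdata", "clinical_panel_demo.tsv",
                             package = "paleokin"))
    }
    doses <- sc[["panel_doses"]] %||% {
      d <- lapply(mat$samples, function(s) rep(0L, nrow(panel)))
      stats::setNames(d, mat$samples)
    }
    pu <- simulate_pileup(panel, doses, coverage = sc[["pileup_coverage"]] %||% 1,
                          cfg = cfg)
    paths$pileup <- file.path(out_dir, "pileup.tsv")
    write_pileup(pu, paths$pileup)
    paths$panel <- file.path(out_dir, "panel.tsv")
    write_panel(panel, paths$panel)
  }

  sex_calls <- NULL
  if ("ploidy" %in% stages) {
    pc <- config[["ploidy"]] %||% list()
    depth_path <- pc[["depths"]] %||% paths$depths
    tables <- read_depth_tables(depth_path)
    ref_src <- pc[["refs"]]
    if (is.null(ref_src)) {
      # build references from simulated normal genomes
      ref_karyos <- c(rep("XX", 10), rep("XY", 10))
      names(ref_karyos) <- sprintf("ref%02d", seq_along(ref_karyos))
      sm <- default_site_map(pc[["ref_sites"]] %||% 100000)
      refs <- lapply(names(ref_karyos), function(s) {
        simulate_depth_table(ref_karyos[[s]], sm, coverage = 0.1,
                             seed = seed + 500 + match(s, names(ref_karyos)),
                             sample = s)
      })
    } else {
      refs <- read_depth_tables(ref_src)
      ref_karyos <- read_karyotypes(pc[["ref_karyotypes"]])
    }
    rs <- build_reference_stats(refs, ref_karyos)
    kcalls <- lapply(tables, function(d) {
      pl <- estimate_ploidy(d, rs, z_threshold = pc[["z"]] %||% 3)
      call_karyotype(pl, min_reads = pc[["min_reads"]] %||% 100)
    })
    kt <- data.frame(
      sample = vapply(kcalls, function(k) k$sample, character(1)),
      gonosomal = vapply(kcalls, function(k) k$gonosomal, character(1)),
      genetic_sex = vapply(kcalls, function(k) k$genetic_sex, character(1)),
      trisomies = vapply(kcalls, function(k)
        paste(k$autosomal_trisomies, collapse = ","), character(1)),
      monosomies = vapply(kcalls, function(k)
        paste(k$autosomal_monosomies, collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    rownames(kt) <- NULL
    paths$karyotypes <- file.path(out_dir, "karyotypes.tsv")
    utils::write.table(kt, paths$karyotypes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logf("ploidy: %d samples called", nrow(kt))
    sex_calls <- kt
  }

  if ("kinship" %in% stages) {
    kc <- config[["kinship"]] %||% list()
    prefix <- kc[["geno_prefix"]] %||% paths$geno_prefix
    mat <- read_eigenstrat(prefix)
    est <- kin_matrix(mat, min_overlap = kc[["min_overlap"]] %||% 1000,
                      background_mode = kc[["background"]] %||% "median",
                      background_value = kc[["background_value"]])
    paths$kinship <- file.path(out_dir, "kinship_pairs.tsv")
    utils::write.table(est, paths$kinship, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    net <- build_network(est, nodes = mat$samples)
    el <- igraph::as_data_frame(net, what = "edges")
    paths$network <- file.path(out_dir, "kinship_edges.tsv")
    utils::write.table(el, paths$network, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logf("kinship: %d pairs, %d related edges", nrow(est), nrow(el))
  }

  if ("screen" %in% stages) {
    scn <- config[["screen"]] %||% list()
    pu <- read_pileup(scn[["pileup"]] %||% paths$pileup)
    panel <- read_panel(scn[["panel"]] %||% paths$panel)
    hits <- screen_sample(pu, panel)
    hits <- apply_damage_filter(hits,
                                min_alt_reads = scn[["min_alt_reads"]] %||% 2,
                                cross_sample = scn[["cross_sample"]] %||% TRUE)
    paths$hits <- file.path(out_dir, "variant_hits.tsv")
    utils::write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$screen_report <- file.path(out_dir, "screen_report.tsv")
    utils::write.table(summarize_report(hits), paths$screen_report,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("screen: %d hits (%d retained)", nrow(hits),
         sum(hits$status == "retained"))
  }

  if ("report" %in% stages && !is.null(sex_calls)) {
    groups <- config[["groups"]] %||%
      stats::setNames(rep("cohort", nrow(sex_calls)), sex_calls$sample)
    summ <- aggregate_sex(data.frame(sample = sex_calls$sample,
                                     group = groups[sex_calls$sample],
                                     sex = sex_calls$genetic_sex,
                                     stringsAsFactors = FALSE))
    paths$summary <- file.path(out_dir, "cohort_summary.tsv")
    utils::write.table(summ, paths$summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logf("report: %d group(s)", nrow(summ))
  }
  invisible(paths)
}

#' A small demonstration pedigree
#'
#' Two unrelated founder couples, a nuclear family with two full siblings
#' (a dizygotic-twin configuration), a half-sibling via a second mating,
#' and one duplicated individual.
#' @return a \code{\link{pedigree_spec}}.
#' @export
demo_pedigree <- function() {
  pedigree_spec(
    founders = c("F1", "M1", "F2", "M2"),
    matings = data.frame(
      parent_a = c("F1", "F1", "F2"),
      parent_b = c("M1", "M1", "M1"),
      child = c("C1", "C2", "C3")),
    duplicates = data.frame(source = "C1", copy = "C1dup")
  )
}
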